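# Repertoire feature panel and group-comparison statistics: Fisher 2x2 for
# categorical gene-usage parameters, Welch t for continuous ones, Pearson
# correlation matrices with Benjamini-Hochberg control.

#' CDR3 net-charge class
#'
#' Net charge at neutral pH counts R and K as +1 and D and E as -1
#' (histidine excluded). Class is positive/negative for net charge above/
#' below zero, neutral otherwise.
#'
#' @param cdr3_aa character vector of CDR3 amino-acid sequences.
#' @return character vector in {"positive", "neutral", "negative"}.
#' @export
cdr3_charge_class <- function(cdr3_aa) {
  vapply(cdr3_aa, function(s) {
    ch <- strsplit(s, "")[[1]]
    if (any(!ch %in% AA_CHARS)) {
      stop("non-amino-acid character in CDR3: ", s)
    }
    net <- sum(ch %in% c("R", "K")) - sum(ch %in% c("D", "E"))
    if (net > 0) "positive" else if (net < 0) "negative" else "neutral"
  }, character(1), USE.NAMES = FALSE)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact two-sided p-value with the probability-at-most-observed rule: the
#' sum of hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table
#' (computed in log space, no normal approximation). The table is
#' (a b / c d) with rows as groups.
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if (sum(cells) == 0) return(1)
  m <- a + b; n <- c + d; k <- a + c
  support <- max(0, k - n):min(k, m)
  logp <- dhyper(support, m, n, k, log = TRUE)
  obs <- dhyper(a, m, n, k, log = TRUE)
  # relative tolerance guards against ties lost to floating point
  qualify <- logp <= obs + 1e-7
  if (all(qualify)) return(1)       # observed table is the mode
  min(1, sum(exp(logp[qualify])))
}

#' Welch's two-sample t test
#'
#' Unpaired two-tailed t test with Welch's correction (Satterthwaite
#' degrees of freedom). Degenerate input (both samples constant with equal
#' means) returns t = 0, p = 1.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return list: `t`, `df`, `p`.
#' @export
welch_t <- function(x, y) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
    }
    return(list(t = if (mean(x) > mean(y)) Inf else -Inf,
                df = length(x) + length(y) - 2, p = 0))
  }
  ht <- t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Build a repertoire feature panel
#'
#' Enumerates per-sequence categorical features (V family, V gene, J gene,
#' V-J pairing, isotype, CDR3 charge class, CDR3 length class) and
#' continuous features (CDR3 length, V_H mutation count). When a paired
#' single-cell table is supplied (columns `d_family`, `light_v_call`,
#' `light_j_call`, `light_cdr3_aa`, `light_mutation_count` as available),
#' D-family, light-chain and heavy-light pairing features are added.
#'
#' @param records annotated, QC-passed rearrangement data.frame.
#' @param paired optional single-cell paired-chain data.frame aligned to
#'   `records` rows.
#' @return list of class `"feature_panel"`: `cat` (long data.frame of
#'   feature/value per sequence), `cont` (named list of numeric vectors),
#'   `n` (number of sequences).
#' @export
build_feature_panel <- function(records, paired = NULL) {
  n <- nrow(records)
  ok_cdr3 <- !is.na(records$junction_aa)
  cat_feats <- list(
    v_family = family_of(records$v_call),
    v_gene = gene_of(records$v_call),
    j_gene = gene_of(records$j_call),
    vj_pair = paste(gene_of(records$v_call), gene_of(records$j_call),
                    sep = ":"),
    isotype = ifelse(records$c_call == "", "unknown", records$c_call),
    cdr3_charge = ifelse(ok_cdr3, NA, NA))
  cat_feats$cdr3_charge[ok_cdr3] <- cdr3_charge_class(records$junction_aa[ok_cdr3])
  len <- records$cdr3_length_aa
  cat_feats$cdr3_length_class <- cut(len, c(-Inf, 9, 14, Inf),
                                     labels = c("short", "medium", "long"))
  cont <- list(cdr3_length_aa = records$cdr3_length_aa,
               vh_mutation_count = records$vh_mutation_count)
  if (!is.null(paired)) {
    if ("d_family" %in% names(paired)) cat_feats$d_family <- paired$d_family
    if ("light_v_call" %in% names(paired)) {
      cat_feats$light_v_family <- family_of(paired$light_v_call)
      cat_feats$hl_pair <- paste(family_of(records$v_call),
                                 family_of(paired$light_v_call), sep = ":")
    }
    if (all(c("light_v_call", "light_j_call") %in% names(paired))) {
      cat_feats$light_vj_pair <- paste(gene_of(paired$light_v_call),
                                       gene_of(paired$light_j_call),
                                       sep = ":")
    }
    if ("light_cdr3_aa" %in% names(paired)) {
      cat_feats$light_cdr3_charge <- cdr3_charge_class(paired$light_cdr3_aa)
    }
    if ("light_mutation_count" %in% names(paired)) {
      cont$light_mutation_count <- paired$light_mutation_count
    }
  }
  cat_long <- do.call(rbind, lapply(names(cat_feats), function(f) {
    data.frame(feature = f, value = as.character(cat_feats[[f]]),
               stringsAsFactors = FALSE)
  }))
  cat_long <- cat_long[!is.na(cat_long$value), , drop = FALSE]
  structure(list(cat = cat_long, cont = cont, n = n),
            class = "feature_panel")
}

#' Compare two repertoire feature panels
#'
#' Every categorical (feature, level) pair observed in either panel is
#' tested by [fisher_exact_2x2()] on (count in group, rest of group);
#' continuous features by [welch_t()]. Effects are first-group minus
#' second-group frequencies (or means). The significance flag uses the
#' unadjusted p < alpha cut; Benjamini-Hochberg adjusted p-values are
#' reported alongside.
#'
#' @param panel_a,panel_b [build_feature_panel()] results (conventionally
#'   eART and lART).
#' @param alpha unadjusted significance cut (default 0.05).
#' @return data.frame, one row per tested parameter: feature, level, test,
#'   effect, p, bh_p, neglog10_p, significant.
#' @export
compare_repertoires <- function(panel_a, panel_b, alpha = 0.05) {
  count_level <- function(panel, f, v) {
    sum(panel$cat$feature == f & panel$cat$value == v)
  }
  keys <- unique(rbind(panel_a$cat, panel_b$cat)[, c("feature", "value")])
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    f <- keys$feature[i]; v <- keys$value[i]
    a <- count_level(panel_a, f, v); cc <- count_level(panel_b, f, v)
    if (a == 0 && cc == 0) {
      message("skipping parameter absent from both groups: ", f, "=", v)
      next
    }
    p <- fisher_exact_2x2(a, panel_a$n - a, cc, panel_b$n - cc)
    rows[[length(rows) + 1]] <- data.frame(
      feature = f, level = v, test = "fisher_2x2",
      effect = a / panel_a$n - cc / panel_b$n, p = p,
      stringsAsFactors = FALSE)
  }
  for (f in union(names(panel_a$cont), names(panel_b$cont))) {
    x <- panel_a$cont[[f]]; y <- panel_b$cont[[f]]
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) < 2 || length(y) < 2) next
    wt <- welch_t(x, y)
    rows[[length(rows) + 1]] <- data.frame(
      feature = f, level = "", test = "welch_t",
      effect = mean(x) - mean(y), p = wt$p, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$feature, out$level), , drop = FALSE]
  out$bh_p <- p.adjust(out$p, method = "BH")
  out$neglog10_p <- -log10(out$p)
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' Pairwise Pearson correlation matrix with BH control
#'
#' Pearson r and two-sided p per column pair over pairwise-complete
#' observations. Constant columns yield NA with a warning. BH-adjusted
#' p-values are reported per pair, together with the largest raw p passing
#' BH at level `q` (the corrected significance threshold).
#'
#' @param x numeric data.frame or matrix (observations x variables).
#' @param q BH false-discovery level (default 0.05).
#' @return list: `r`, `p`, `bh_p` (matrices), `pairs` (long data.frame),
#'   `bh_threshold`.
#' @export
correlation_matrix <- function(x, q = 0.05) {
  x <- as.data.frame(x)
  vars <- names(x)
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  diag(r) <- 1
  pairs <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    xi <- x[[i]]; xj <- x[[j]]
    ok <- complete.cases(xi, xj)
    if (sum(ok) < 3 || stats::sd(xi[ok]) == 0 || stats::sd(xj[ok]) == 0) {
      warning("correlation undefined for pair (", vars[i], ", ", vars[j],
              "): constant or insufficient data")
      pairs[[length(pairs) + 1]] <- data.frame(
        var1 = vars[i], var2 = vars[j], r = NA_real_, p = NA_real_,
        stringsAsFactors = FALSE)
      next
    }
    ct <- cor.test(xi[ok], xj[ok], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
    pairs[[length(pairs) + 1]] <- data.frame(
      var1 = vars[i], var2 = vars[j], r = unname(ct$estimate),
      p = ct$p.value, stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, pairs)
  pairs$bh_p <- p.adjust(pairs$p, method = "BH")
  bh_p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (row in seq_len(nrow(pairs))) {
    bh_p[pairs$var1[row], pairs$var2[row]] <-
      bh_p[pairs$var2[row], pairs$var1[row]] <- pairs$bh_p[row]
  }
  rejected <- !is.na(pairs$bh_p) & pairs$bh_p <= q
  bh_threshold <- if (any(rejected)) max(pairs$p[rejected]) else NA_real_
  list(r = r, p = p, bh_p = bh_p, pairs = pairs,
       bh_threshold = bh_threshold)
}

#' IgA/IgG ratio of a repertoire
#'
#' @param records annotated, QC-passed rearrangement data.frame.
#' @param group optional group label to subset on.
#' @return count(IGA)/count(IGG); infinite (with a warning) when no IGG
#'   records exist.
#' @export
iga_igg_ratio <- function(records, group = NULL) {
  if (!is.null(group)) {
    records <- records[records$group == group, , drop = FALSE]
  }
  n_a <- sum(records$c_call == "IGA")
  n_g <- sum(records$c_call == "IGG")
  if (n_g == 0) {
    warning("no IGG records; IgA/IgG ratio is infinite")
    return(Inf)
  }
  n_a / n_g
}
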