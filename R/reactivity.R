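# ELISA binding-curve summaries and protein-microarray polyreactivity
# scoring.

#' Area under an ELISA binding curve
#'
#' Trapezoidal integral of OD405 against log10(concentration). Negative
#' ODs (over-subtracted background) are clamped to zero before
#' integration.
#'
#' @param concentration antibody concentrations (same unit throughout).
#' @param od background-subtracted OD405 values.
#' @return AUC in OD x log10(concentration) units.
#' @export
curve_auc <- function(concentration, od) {
  if (length(concentration) < 2 || length(od) != length(concentration)) {
    stop("need at least 2 (concentration, OD) points")
  }
  if (any(!is.finite(od))) stop("OD values must be finite")
  x <- log10(concentration)
  o <- order(x)
  x <- x[o]; y <- pmax(od[o], 0)
  sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Cumulative AUC over an antigen panel
#'
#' CAUC = log10(sum of per-antigen AUCs + 1); the +1 offset pins a
#' zero-binding antibody at CAUC 0.
#'
#' @param aucs per-antigen AUC values for one antibody.
#' @return CAUC.
#' @export
cumulative_auc <- function(aucs) {
  if (length(aucs) == 0) stop("empty antigen panel")
  log10(sum(aucs) + 1)
}

#' Robust per-array Z-scores from a microarray spot table
#'
#' Duplicate spots are averaged, then each array (test and reference
#' antibody) is scored as Z_i = (MFI_i - median) / (1.4826 * MAD).
#'
#' @param spots data.frame with columns `protein_id`, `mfi_test_rep1`,
#'   `mfi_test_rep2`, `mfi_ref_rep1`, `mfi_ref_rep2`.
#' @return data.frame of class `"microarray_profile"`: `protein_id`,
#'   `z_test`, `z_ref`.
#' @export
microarray_zscores <- function(spots) {
  need <- c("protein_id", "mfi_test_rep1", "mfi_test_rep2",
            "mfi_ref_rep1", "mfi_ref_rep2")
  miss <- setdiff(need, names(spots))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  zscore <- function(v) {
    s <- mad(v)               # default constant 1.4826
    if (s == 0) {
      stop("MAD is zero: degenerate array (all spots identical)")
    }
    (v - median(v)) / s
  }
  test <- (spots$mfi_test_rep1 + spots$mfi_test_rep2) / 2
  ref <- (spots$mfi_ref_rep1 + spots$mfi_ref_rep2) / 2
  out <- data.frame(protein_id = spots$protein_id,
                    z_test = zscore(test), z_ref = zscore(ref),
                    stringsAsFactors = FALSE)
  class(out) <- c("microarray_profile", "data.frame")
  out
}

#' Polyreactivity index from a microarray profile
#'
#' For each protein the deviation to the test = reference diagonal is
#' sigma_i = (Z_test,i - Z_ref,i) / sqrt(2) (perpendicular distance,
#' signed towards the test antibody). PI is the fraction of proteins with
#' sigma_i > `sigma_cut`; the antibody is polyreactive when PI is strictly
#' greater than `pi_cut`.
#'
#' @param profile a [microarray_zscores()] result (needs `z_test`,
#'   `z_ref`).
#' @param sigma_cut diagonal deviation band (default 2).
#' @param pi_cut classification threshold (default 0.21, strict
#'   inequality).
#' @return list: `sigma` (per-protein deviations), `pi`, `polyreactive`.
#' @export
polyreactivity_index <- function(profile, sigma_cut = 2, pi_cut = 0.21) {
  if (!all(c("z_test", "z_ref") %in% names(profile))) {
    stop("profile lacks Z-scores; run microarray_zscores() first")
  }
  sigma <- (profile$z_test - profile$z_ref) / sqrt(2)
  pi <- mean(sigma > sigma_cut)
  list(sigma = sigma, pi = pi, polyreactive = pi > pi_cut)
}
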