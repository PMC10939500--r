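#' Droplet-digital PCR droplet counts
#'
#' @param droplets total droplets read (>= 1).
#' @param fam_positive droplets positive in the FAM channel.
#' @param hex_positive droplets positive in the HEX channel.
#' @return object of class `droplet_counts`.
#' @export
droplet_counts <- function(droplets, fam_positive, hex_positive) {
  droplets <- check_count(droplets, "droplets", min = 1L)
  fam_positive <- check_count(fam_positive, "fam_positive")
  hex_positive <- check_count(hex_positive, "hex_positive")
  if (fam_positive > droplets || hex_positive > droplets) {
    cm_stop("positive count exceeds droplet count", "invalid_parameter")
  }
  structure(list(droplets = droplets, fam_positive = fam_positive,
                 hex_positive = hex_positive), class = "droplet_counts")
}

#' Poisson concentration estimate for digital PCR
#'
#' Mean template copies per droplet from the fraction of positive droplets,
#' by Poisson occupancy: `lambda = -log(1 - positives / droplets)`.
#'
#' @param droplets total droplets.
#' @param positives positive droplets, `0 <= positives < droplets`.
#' @return estimated copies per droplet (>= 0).
#' @examples
#' poisson_lambda(20000, 10000)  # log(2)
#' @export
poisson_lambda <- function(droplets, positives) {
  droplets <- check_count(droplets, "droplets", min = 1L)
  positives <- check_count(positives, "positives")
  if (positives > droplets) {
    cm_stop("positives exceed droplet count", "invalid_input")
  }
  if (positives == droplets) {
    cm_stop("all droplets positive: concentration saturated", "saturation")
  }
  -log(1 - positives / droplets)
}

# delta-method variance of lambda-hat: Var(p-hat)/(1-p)^2 with binomial p-hat
lambda_variance <- function(droplets, positives) {
  p <- positives / droplets
  (p * (1 - p) / droplets) / (1 - p)^2
}

#' Allelic fraction from duplex ddPCR counts
#'
#' Per-channel concentrations by Poisson occupancy and the FAM allelic
#' fraction `lambda_fam / (lambda_fam + lambda_hex)`, with a 95% confidence
#' interval by first-order (delta-method) propagation of the binomial
#' sampling variance of each positive proportion.
#'
#' @param counts a [droplet_counts()].
#' @param conf_level confidence level for the interval.
#' @return object of class `allelic_result`: list with `lambda_fam`,
#'   `lambda_hex`, `fraction_fam`, `ci_low`, `ci_high`.
#' @export
allelic_fraction <- function(counts, conf_level = 0.95) {
  stopifnot(inherits(counts, "droplet_counts"))
  if (counts$fam_positive == 0L && counts$hex_positive == 0L) {
    cm_stop("no positive droplets in either channel: fraction undefined",
            "undefined_fraction")
  }
  lf <- poisson_lambda(counts$droplets, counts$fam_positive)
  lh <- poisson_lambda(counts$droplets, counts$hex_positive)
  f <- lf / (lf + lh)
  vf <- lambda_variance(counts$droplets, counts$fam_positive)
  vh <- lambda_variance(counts$droplets, counts$hex_positive)
  # f = lf/(lf+lh): df/dlf = lh/s^2, df/dlh = -lf/s^2 with s = lf + lh
  s <- lf + lh
  var_f <- (lh^2 * vf + lf^2 * vh) / s^4
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  hw <- z * sqrt(var_f)
  structure(list(lambda_fam = lf, lambda_hex = lh, fraction_fam = f,
                 ci_low = max(0, f - hw), ci_high = min(1, f + hw)),
            class = "allelic_result")
}

#' @export
print.allelic_result <- function(x, ...) {
  cat(sprintf("FAM fraction %.4f [%.4f, %.4f]  (lambda FAM %.4g, HEX %.4g)\n",
              x$fraction_fam, x$ci_low, x$ci_high, x$lambda_fam, x$lambda_hex))
  invisible(x)
}

#' Allele-specific expression change relative to a genomic-DNA balance control
#'
#' Compares the FAM:HEX concentration ratio in an edited (cDNA) sample to the
#' same ratio in a genomic-DNA control, which calibrates probe imbalance.
#' Returns the signed percent change of the FAM-tracked allele: negative
#' values are a decrease (e.g. -50 means the edited allele is expressed at
#' half the control-calibrated level).
#'
#' @param edited an [allelic_fraction()] result for the expression sample.
#' @param control_balance an [allelic_fraction()] result for the genomic-DNA
#'   calibration sample (fraction strictly inside (0, 1)).
#' @return signed percent change.
#' @export
expression_change <- function(edited, control_balance) {
  stopifnot(inherits(edited, "allelic_result"),
            inherits(control_balance, "allelic_result"))
  if (control_balance$fraction_fam <= 0 || control_balance$fraction_fam >= 1) {
    cm_stop("control balance fraction must lie strictly in (0, 1)",
            "invalid_parameter")
  }
  if (edited$lambda_hex == 0 || control_balance$lambda_hex == 0) {
    cm_stop("zero denominator channel concentration", "invalid_parameter")
  }
  r_e <- edited$lambda_fam / edited$lambda_hex
  r_c <- control_balance$lambda_fam / control_balance$lambda_hex
  100 * (r_e / r_c - 1)
}

#' Analyze a table of ddPCR samples
#'
#' Computes per-sample concentrations and allelic fractions and, where a
#' `role` column marks `control` and `edited` samples, the percent expression
#' change of each edited sample against the mean control ratio.
#'
#' @param counts_df data.frame with columns `sample_id, droplets,
#'   fam_positive, hex_positive` and optionally `role` (`control`/`edited`).
#' @return data.frame with per-sample `lambda_fam`, `lambda_hex`,
#'   `fraction_fam`, `ci_low`, `ci_high`, and `percent_change` (NA for
#'   controls or when no control present).
#' @export
analyze_ddpcr <- function(counts_df) {
  need <- c("sample_id", "droplets", "fam_positive", "hex_positive")
  if (!all(need %in% names(counts_df))) {
    cm_stop(paste("counts table must have columns:",
                  paste(need, collapse = ", ")), "parse_error")
  }
  res <- lapply(seq_len(nrow(counts_df)), function(i)
    allelic_fraction(droplet_counts(counts_df$droplets[i],
                                    counts_df$fam_positive[i],
                                    counts_df$hex_positive[i])))
  out <- cbind(counts_df,
               lambda_fam = vapply(res, `[[`, numeric(1), "lambda_fam"),
               lambda_hex = vapply(res, `[[`, numeric(1), "lambda_hex"),
               fraction_fam = vapply(res, `[[`, numeric(1), "fraction_fam"),
               ci_low = vapply(res, `[[`, numeric(1), "ci_low"),
               ci_high = vapply(res, `[[`, numeric(1), "ci_high"))
  out$percent_change <- NA_real_
  if ("role" %in% names(counts_df) && any(counts_df$role == "control")) {
    ctrl <- which(counts_df$role == "control")
    # average the control ratio on the log scale (ratios are multiplicative)
    r_c <- exp(mean(log(out$lambda_fam[ctrl] / out$lambda_hex[ctrl])))
    edited <- which(counts_df$role == "edited")
    r_e <- out$lambda_fam[edited] / out$lambda_hex[edited]
    out$percent_change[edited] <- 100 * (r_e / r_c - 1)
  }
  out
}
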