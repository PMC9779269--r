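#' Map agreement: confusion matrix, overall accuracy and kappa
#'
#' Compares a simulated categorical map against the observed one over the
#' jointly valid cells. Overall accuracy P0 is the trace share of the
#' confusion matrix; chance agreement Pc is the marginal product sum
#' (Cohen's convention, with the ideal accuracy Pp = 1), and
#' `kappa = (P0 - Pc) / (Pp - Pc)`. Agreement bands follow the usual
#' thresholds: kappa > 0.75 high, 0.4-0.75 general, < 0.4 poor.
#'
#' @param actual,simulated aligned [lulc_raster]s sharing a legend.
#' @return object of class `agreement_report` with fields `confusion`, `p0`,
#'   `pc`, `pp`, `kappa`, `band`.
#' @export
agreement <- function(actual, simulated) {
  ct <- crosstab(actual, simulated)
  cm <- ct$counts
  total <- sum(cm)
  if (total == 0) stop("no jointly valid cells to compare")
  p0 <- sum(diag(cm)) / total
  pc <- sum(rowSums(cm) * colSums(cm)) / total^2
  pp <- 1
  kappa <- if (abs(pp - pc) < .Machine$double.eps) 1 else (p0 - pc) / (pp - pc)
  band <- if (kappa > 0.75) "high" else if (kappa >= 0.4) "general" else "poor"
  structure(list(confusion = cm, p0 = p0, pc = pc, pp = pp,
                 kappa = kappa, band = band),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(
    "<agreement_report> overall accuracy %.4f, kappa %.4f (%s agreement)\n",
    x$p0, x$kappa, x$band))
  invisible(x)
}

#' Write an agreement report as delimited text
#'
#' @param report an `agreement_report`.
#' @param path file path.
#' @export
write_agreement <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("p0,%.6f", report$p0), con)
  writeLines(sprintf("pc,%.6f", report$pc), con)
  writeLines(sprintf("kappa,%.6f", report$kappa), con)
  writeLines(paste0("band,", report$band), con)
  writeLines("confusion:", con)
  utils::write.csv(report$confusion, con)
  invisible(path)
}
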