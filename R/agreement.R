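# Inter-rater agreement statistics for binary annotations: observed
# agreement, Cohen's kappa, prevalence-adjusted bias-adjusted kappa
# (PABAK), and the interpretation bands.

#' Build a 2x2 agreement table
#'
#' Either from the four cell counts, or from two aligned binary label
#' vectors (rater 1 and rater 2).
#'
#' @param a both raters positive; or, with `labels2`, rater 1's labels.
#' @param b rater 1 positive only; or rater 2's labels.
#' @param c rater 2 positive only.
#' @param d both raters negative.
#' @return an `agreement_table` with fields `a`, `b`, `c`, `d`, `N`.
#' @export
agreement_table <- function(a, b, c = NULL, d = NULL) {
  if (is.null(c) && is.null(d) && length(a) > 1L) {
    r1 <- a; r2 <- b
    if (length(r1) != length(r2)) eh_stop("label vectors differ in length", field = "b")
    if (!all(r1 %in% c(0, 1)) || !all(r2 %in% c(0, 1))) {
      eh_stop("labels must be binary", field = "a")
    }
    a <- sum(r1 == 1 & r2 == 1); b <- sum(r1 == 1 & r2 == 0)
    c <- sum(r1 == 0 & r2 == 1); d <- sum(r1 == 0 & r2 == 0)
  }
  cnt <- c(a, b, c, d)
  if (length(cnt) != 4L || anyNA(cnt) || any(cnt < 0)) {
    eh_stop("counts must be four non-negative numbers", field = "a")
  }
  if (sum(cnt) < 1L) eh_stop("table is empty", field = "a")
  structure(list(a = a, b = b, c = c, d = d, N = sum(cnt)),
            class = "agreement_table")
}

#' Observed agreement
#' @param t an [agreement_table()].
#' @return `(a + d) / N`, in \[0, 1\].
#' @export
observed_agreement <- function(t) {
  stopifnot(inherits(t, "agreement_table"))
  (t$a + t$d) / t$N
}

#' Cohen's kappa for a 2x2 table
#'
#' `(p_o - p_e) / (1 - p_e)` with chance agreement
#' `p_e = ((a+b)(a+c) + (c+d)(b+d)) / N^2`. The degenerate case `p_e = 1`
#' (both raters constant) is defined as 1 when observed agreement is
#' perfect and 0 otherwise.
#'
#' @param t an [agreement_table()].
#' @return kappa in \[-1, 1\].
#' @export
cohen_kappa <- function(t) {
  stopifnot(inherits(t, "agreement_table"))
  p_o <- observed_agreement(t)
  p_e <- ((t$a + t$b) * (t$a + t$c) + (t$c + t$d) * (t$b + t$d)) / t$N^2
  if (p_e >= 1) return(if (p_o == 1) 1 else 0)
  (p_o - p_e) / (1 - p_e)
}

#' Prevalence-adjusted bias-adjusted kappa (PABAK)
#'
#' `2 * p_o - 1`: kappa computed as if prevalence were balanced and the
#' raters unbiased, so it depends on the table only through the observed
#' agreement.
#'
#' @param t an [agreement_table()].
#' @return PABAK in \[-1, 1\].
#' @export
pabak <- function(t) {
  2 * observed_agreement(t) - 1
}

#' Interpretation band for a kappa-type coefficient
#'
#' Bands (lower edges inclusive): below 0 poor; 0-0.21 slight; 0.21-0.41
#' fair; 0.41-0.61 moderate; 0.61-0.81 substantial; 0.81-1 almost perfect.
#'
#' @param value coefficient in \[-1, 1\].
#' @return band label.
#' @export
interpret_kappa <- function(value) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) ||
      value < -1 || value > 1) {
    eh_stop("must be a single value in [-1, 1]", field = "value")
  }
  if (value < 0) "poor"
  else if (value < 0.21) "slight"
  else if (value < 0.41) "fair"
  else if (value < 0.61) "moderate"
  else if (value < 0.81) "substantial"
  else "almost perfect"
}

#' Agreement summary for two aligned annotation tracks
#'
#' @param labels1,labels2 binary label vectors aligned on the same
#'   (participant, task, frame, hand) instances.
#' @return data frame with `N`, `p_o`, `kappa`, `PABAK`, `kappa_band`,
#'   `pabak_band` (one row), mirroring a reliability-table row.
#' @export
rate_agreement <- function(labels1, labels2) {
  t <- agreement_table(labels1, labels2)
  k <- cohen_kappa(t)
  pb <- pabak(t)
  data.frame(N = t$N, p_o = observed_agreement(t), kappa = k, PABAK = pb,
             kappa_band = interpret_kappa(k), pabak_band = interpret_kappa(pb),
             stringsAsFactors = FALSE)
}
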