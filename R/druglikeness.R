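## Drug-likeness profiling: Lipinski rule-of-5 violation counts and QED.

# Asymmetric double sigmoid (ADS) desirability parameters of the QED model
# (Bickerton et al.), one row per descriptor, plus the published mean
# weights. d(x) = [A + B/(1+exp(-(x-C+D/2)/E)) * (1 - 1/(1+exp(-(x-C-D/2)/F)))] / DMAX
.qed_ads <- data.frame(
  row.names = c("MW", "ALOGP", "HBA", "HBD", "PSA", "ROTB", "AROM", "ALERTS"),
  A = c(2.817065973, 3.172690585, 2.948620388, 1.618662227, 1.876861559,
        0.01, 3.21778897, 0.01),
  B = c(392.5754953, 137.8624751, 160.4605972, 1010.051101, 125.2232657,
        272.4121427, 957.7374108, 1199.094025),
  C = c(290.7489764, 2.534937431, 3.615294657, 0.985094388, 62.90773554,
        2.55837997, 2.274627939, -0.09002883),
  D = c(2.419764353, 4.581497897, 4.435986202, 1e-09, 87.83366614,
        1.565547684, 1e-09, 1e-09),
  E = c(49.22325677, 0.822739154, 0.290141953, 0.713820843, 12.01999824,
        1.271567166, 1.317690384, 0.185904477),
  F = c(65.37051707, 0.576295591, 1.300669958, 0.920922555, 28.51324732,
        2.758063707, 0.375760881, 0.875193782),
  DMAX = c(104.9805561, 131.3186604, 148.7763046, 258.1632616, 104.5686167,
           105.4420403, 312.337261, 417.725314))

.qed_weights <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                  PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

.ads <- function(x, p) {
  d <- (p$A + p$B / (1 + exp(-(x - p$C + p$D / 2) / p$E)) *
          (1 - 1 / (1 + exp(-(x - p$C - p$D / 2) / p$F)))) / p$DMAX
  pmin(pmax(d, 0), 1)
}

#' Weighted QED from the eight raw descriptors
#'
#' The quantitative estimate of drug-likeness: each descriptor (molecular
#' weight, ALOGP, HBA, HBD, polar surface area, rotatable bonds, aromatic
#' rings, structural alerts) is mapped through its asymmetric
#' double-sigmoid desirability function and the scores are combined as a
#' weighted geometric mean with the published mean weights.
#'
#' @param props `data.frame`/list with columns `qed_mw`, `qed_alogp`,
#'   `qed_hba`, `qed_hbd`, `qed_psa`, `qed_rotb`, `qed_arom`, `qed_alerts`
#'   (as returned by [raw_descriptors()]).
#' @param weights Named weights over the eight descriptors (defaults to the
#'   published mean weights).
#' @return Numeric vector of QED values in (0, 1].
#' @export
qed_score <- function(props, weights = .qed_weights) {
  cols <- c(MW = "qed_mw", ALOGP = "qed_alogp", HBA = "qed_hba",
            HBD = "qed_hbd", PSA = "qed_psa", ROTB = "qed_rotb",
            AROM = "qed_arom", ALERTS = "qed_alerts")
  stopifnot(all(cols %in% names(props)),
            setequal(names(weights), names(cols)))
  logsum <- 0
  for (nm in names(cols)) {
    d <- .ads(as.numeric(props[[cols[[nm]]]]), .qed_ads[nm, ])
    logsum <- logsum + weights[[nm]] * log(d)
  }
  exp(logsum / sum(weights))
}

#' Per-molecule property profiles
#'
#' Computes, for every sanitizable molecule: average molecular weight,
#' Crippen clogP, Lipinski HBD/HBA counts, the rule-of-5 violation count
#' ro5vc = |{MW > 500, clogP > 5, HBD > 5, HBA > 10}| (strict
#' inequalities), and the weighted QED. Unsanitizable inputs yield `NA`
#' rows with `ok = FALSE` rather than aborting the batch.
#'
#' @param smiles Character vector of SMILES.
#' @return `data.frame` with columns `smiles`, `ok`, `mw`, `clogp`, `hbd`,
#'   `hba`, `ro5vc`, `qed`.
#' @export
profile_molecules <- function(smiles) {
  d <- raw_descriptors(smiles)
  ro5vc <- as.integer((d$mw > 500) + (d$clogp > 5) +
                        (d$hbd > 5) + (d$hba > 10))
  data.frame(smiles = smiles, ok = d$ok,
             mw = d$mw, clogp = d$clogp, hbd = d$hbd, hba = d$hba,
             ro5vc = ro5vc, qed = qed_score(d),
             stringsAsFactors = FALSE)
}

#' Library-level drug-likeness summary
#'
#' @param profiles `data.frame` from [profile_molecules()] (rows with
#'   `ok = FALSE` are dropped first).
#' @return List of class `cddap_summary`: `n`, `ro5vc_fractions` (named,
#'   levels 0--4, summing to 1), `mean_qed`, `median_qed` (midpoint
#'   convention for even n), `mean_mw`, `frac_mw_lt_500`, and
#'   `qed_histogram` (counts in bins of width 0.1 over \[0, 1\]).
#' @export
summarize_library <- function(profiles) {
  if ("ok" %in% names(profiles)) {
    profiles <- profiles[profiles$ok, , drop = FALSE]
  }
  n <- nrow(profiles)
  if (n == 0) stop("summarize_library(): no profiles")
  fr <- tabulate(profiles$ro5vc + 1L, nbins = 5L) / n
  names(fr) <- as.character(0:4)
  breaks <- seq(0, 1, by = 0.1)
  hist_counts <- tabulate(pmin(findInterval(profiles$qed, breaks,
                                            rightmost.closed = TRUE), 10L),
                          nbins = 10L)
  names(hist_counts) <- sprintf("(%.1f,%.1f]", breaks[1:10], breaks[2:11])
  out <- list(n = n,
              ro5vc_fractions = fr,
              mean_qed = mean(profiles$qed),
              median_qed = stats::median(profiles$qed),
              mean_mw = mean(profiles$mw),
              frac_mw_lt_500 = mean(profiles$mw < 500),
              qed_histogram = hist_counts)
  class(out) <- "cddap_summary"
  out
}

#' @export
print.cddap_summary <- function(x, ...) {
  cat("Library summary (n = ", x$n, ")\n", sep = "")
  cat("  Ro5 violation fractions:",
      paste(sprintf("%s: %.1f%%", names(x$ro5vc_fractions),
                    100 * x$ro5vc_fractions), collapse = ", "), "\n")
  cat(sprintf("  mean QED %.3f, median QED %.3f\n", x$mean_qed, x$median_qed))
  cat(sprintf("  mean MW %.1f, MW < 500: %.1f%%\n",
              x$mean_mw, 100 * x$frac_mw_lt_500))
  invisible(x)
}

#' Pearson product-moment correlation
#'
#' Direct sum-formula implementation (the test suite checks it against an
#' independent oracle). Used in the pipeline to correlate Ro5-compliant
#' fractions with mean QED across libraries, and occupancy rates with mean
#' QED.
#'
#' @param xs,ys Numeric vectors of equal length >= 3.
#' @return List with `r` and `r_squared`.
#' @export
pearson_r <- function(xs, ys) {
  stopifnot(length(xs) == length(ys), length(xs) >= 3)
  dx <- xs - mean(xs)
  dy <- ys - mean(ys)
  sx <- sqrt(sum(dx^2))
  sy <- sqrt(sum(dy^2))
  if (sx == 0 || sy == 0) {
    stop("pearson_r(): zero variance, correlation undefined")
  }
  r <- sum(dx * dy) / (sx * sy)
  list(r = r, r_squared = r^2)
}
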