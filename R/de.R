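#' Median-of-ratios size factors
#'
#' For each sample `j`, `s_j` is the median over features `g` of
#' `count(g, j) / geomean_g`, where `geomean_g` is the geometric mean of
#' feature `g` across samples, taken over the features positive in every
#' sample.  When no feature is positive everywhere, the geometric mean is
#' taken over each feature's positive entries instead (with a warning).
#'
#' @param object a [CountDataSet-class] or count matrix.
#' @return positive numeric vector, one factor per sample.
#' @export
sizeFactorsMoR <- function(object) {
  cnt <- if (is(object, "CountDataSet")) counts(object) else as.matrix(object)
  allPos <- rowSums(cnt == 0) == 0L
  if (any(allPos)) {
    sub <- cnt[allPos, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    sf <- apply(sweep(sub, 1L, geo, "/"), 2L, median)
  } else {
    warning("no feature is positive in every sample; ",
            "geometric means taken over positive entries only")
    lg <- log(cnt); lg[!is.finite(lg)] <- NA
    geo <- exp(rowMeans(lg, na.rm = TRUE))
    ok <- is.finite(geo) & geo > 0
    if (!any(ok)) stop("cannot compute size factors: no usable feature")
    ratio <- sweep(cnt[ok, , drop = FALSE], 1L, geo[ok], "/")
    sf <- apply(ratio, 2L, function(v) median(v[v > 0]))
  }
  if (any(!is.finite(sf) | sf <= 0))
    stop("non-positive size factor for sample(s): ",
         paste(head(colnames(cnt)[!is.finite(sf) | sf <= 0], 5L),
               collapse = ", "))
  sf
}

#' Two-class negative-binomial Wald test
#'
#' A self-contained delta-method Wald test on size-factor-normalized class
#' means.  Per feature `g` with normalized class means `m_1`, `m_2`
#' (pseudocount `eps = 0.5`):
#' \deqn{lfc = \log_2\frac{m_2 + \epsilon}{m_1 + \epsilon},\qquad
#'       v_k = \frac{m_k + \phi_g m_k^2}{n_k},\qquad
#'       se = \frac{1}{\ln 2}\sqrt{\frac{v_1}{(m_1+\epsilon)^2} +
#'                                 \frac{v_2}{(m_2+\epsilon)^2}}}
#' with Wald statistic `lfc / se` and a two-sided normal p-value, adjusted
#' by Benjamini-Hochberg.  The dispersion used is the conservative
#' `phi_g = max(gene MoM, trend at the gene's mean)` from
#' [estimateDispersionsMoM()].
#'
#' @param object a [CountDataSet-class] with two classes of >= 2 samples.
#' @param dispersions optional [DispersionEstimates-class]; when omitted,
#'   computed from `object` with `byClass = TRUE` (within-class moments),
#'   so that the class effect under test is not counted as dispersion.
#' @param eps pseudocount on the normalized means (default 0.5).
#' @return a [DEResults-class] (a DataFrame) with columns `baseMean`,
#'   `lfc`, `se`, `wald`, `pvalue`, `qvalue`.
#' @examples
#' cds <- makeFixture("ngssppg1_small", seed = 3)
#' res <- nbWaldTest(cds)
#' countDegs(res)
#' @export
nbWaldTest <- function(object, dispersions = NULL, eps = 0.5) {
  cls <- requireTwoClasses(object, minPerClass = 2L)
  if (is.null(dispersions))
    dispersions <- estimateDispersionsMoM(object, byClass = TRUE)
  stopifnot(is(dispersions, "DispersionEstimates"))
  sf <- sizeFactorsMoR(object)
  norm <- sweep(counts(object), 2L, sf, "/")
  n1 <- sum(cls == 1L); n2 <- sum(cls == 2L)
  m1 <- rowMeans(norm[, cls == 1L, drop = FALSE])
  m2 <- rowMeans(norm[, cls == 2L, drop = FALSE])
  tab <- dispersionTable(dispersions)
  phi <- pmax(tab$phi, tab$trend_value)
  v1 <- (m1 + phi * m1^2) / n1
  v2 <- (m2 + phi * m2^2) / n2
  lfc <- base::log2((m2 + eps) / (m1 + eps))
  se <- sqrt(v1 / (m1 + eps)^2 + v2 / (m2 + eps)^2) / log(2)
  se[se == 0] <- .Machine$double.eps  # all-zero feature in both classes
  wald <- lfc / se
  pvalue <- 2 * pnorm(-abs(wald))
  new("DEResults", S4Vectors::DataFrame(
    baseMean = unname((n1 * m1 + n2 * m2) / (n1 + n2)),
    lfc = unname(lfc), se = unname(se), wald = unname(wald),
    pvalue = unname(pvalue), qvalue = unname(bhAdjust(pvalue)),
    row.names = rownames(object)))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @return monotone (in p-rank) adjusted q-values, capped at 1.
#' @export
bhAdjust <- function(pvalues) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  p.adjust(pvalues, method = "BH")
}

#' Count significant features
#'
#' @param res a [DEResults-class].
#' @param alpha FDR threshold on the q-value (default 0.05).
#' @return integer number of features with `qvalue <= alpha`.
#' @export
countDegs <- function(res, alpha = 0.05) {
  stopifnot(is(res, "DEResults"))
  sum(res$qvalue <= alpha)
}

#' Volcano-plot classification table
#'
#' Classifies every feature by unadjusted p-value and log2 fold change:
#' `nonsig` (p >= `p_thresh`), `sig_small_fc` (significant,
#' `|lfc| <= lfc_thresh`), `sig_up` (significant, `lfc > lfc_thresh`),
#' `sig_down` (significant, `lfc < -lfc_thresh`).
#'
#' @param res a [DEResults-class].
#' @param p_thresh p-value threshold (default 0.05).
#' @param lfc_thresh log2-fold-change threshold (default 1).
#' @param cap ceiling for `-log10(p)`; `p = 0` is mapped to the smallest
#'   positive double before the log (default cap 350).
#' @return data.frame with `feature_id`, `lfc`, `neg_log10_p`, `class`.
#' @export
volcanoTable <- function(res, p_thresh = 0.05, lfc_thresh = 1, cap = 350) {
  stopifnot(is(res, "DEResults"))
  p <- pmax(res$pvalue, .Machine$double.xmin)
  nlp <- pmin(-base::log10(p), cap)
  sig <- res$pvalue < p_thresh
  cls <- rep("nonsig", nrow(res))
  cls[sig & abs(res$lfc) <= lfc_thresh] <- "sig_small_fc"
  cls[sig & res$lfc > lfc_thresh] <- "sig_up"
  cls[sig & res$lfc < -lfc_thresh] <- "sig_down"
  data.frame(feature_id = rownames(res), lfc = res$lfc,
             neg_log10_p = nlp, class = cls, row.names = NULL)
}

#' Sign balance of significant effects
#'
#' Fraction of BH-significant features with positive log2 fold change — a
#' scalar for the "only over-expression present" failure mode visible in
#' skewed volcano plots.
#'
#' @param res a [DEResults-class].
#' @param alpha FDR threshold (default 0.05).
#' @return fraction in `[0, 1]`, or `NaN` (with a warning) when nothing is
#'   significant.
#' @export
signBalance <- function(res, alpha = 0.05) {
  stopifnot(is(res, "DEResults"))
  sig <- res$qvalue <= alpha
  if (!any(sig)) {
    warning("no significant features; sign balance undefined")
    return(NaN)
  }
  mean(res$lfc[sig] > 0)
}

#' Recovery of designed differential expression
#'
#' Compares the BH rejection set at `alpha` with the simulation ground
#' truth: `sensitivity = TP / (designed DE)` and
#' `observed_fdr = FP / max(1, discoveries)` (zero discoveries give 0/0
#' conventions of 0).
#'
#' @param res a [DEResults-class].
#' @param truth logical DE flags (e.g. `deFlags(cds)`), or a
#'   [CountDataSet-class] carrying them.
#' @param alpha FDR threshold (default 0.05).
#' @return list with `sensitivity` and `observed_fdr`.
#' @export
degRecovery <- function(res, truth, alpha = 0.05) {
  stopifnot(is(res, "DEResults"))
  flags <- if (is(truth, "CountDataSet")) deFlags(truth) else as.logical(truth)
  if (is.null(flags) || !any(flags)) stop("ground truth has no DE features")
  stopifnot(length(flags) == nrow(res))
  called <- res$qvalue <= alpha
  tp <- sum(called & flags)
  fp <- sum(called & !flags)
  list(sensitivity = tp / sum(flags),
       observed_fdr = fp / max(1L, sum(called)))
}

#' Export DE results as TSV
#'
#' Columns: `feature_id`, `base_mean`, `lfc`, `se`, `wald`, `pvalue`,
#' `qvalue`, `volcano_class`.
#'
#' @param res a [DEResults-class].
#' @param path output TSV.
#' @param p_thresh,lfc_thresh thresholds for the volcano class column.
#' @export
writeDEResults <- function(res, path, p_thresh = 0.05, lfc_thresh = 1) {
  vt <- volcanoTable(res, p_thresh, lfc_thresh)
  df <- data.frame(feature_id = rownames(res), base_mean = res$baseMean,
                   lfc = res$lfc, se = res$se, wald = res$wald,
                   pvalue = res$pvalue, qvalue = res$qvalue,
                   volcano_class = vt$class)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
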