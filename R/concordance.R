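# Lin's concordance correlation coefficient and transition aggregation.

#' Lin's concordance correlation coefficient
#'
#' `rho_c = 2 * cov(x, y) / (var(x) + var(y) + (mean(x) - mean(y))^2)` with
#' population moments (divisor `n`; set `sample = TRUE` for divisor
#' `n - 1`). Unlike the Pearson correlation, `rho_c` penalizes mean and
#' scale shifts, so it measures agreement, not just linear association.
#' When both vectors are constant the coefficient is undefined and `NA` is
#' returned (callers exclude such features from averages); when exactly one
#' is constant the formula evaluates cleanly to 0.
#'
#' @param x,y numeric vectors of equal length >= 3, all finite.
#' @param sample use sample (n-1) moments instead of population moments.
#' @return a single numeric in `[-1, 1]`, or `NA` if undefined.
#' @examples
#' linsCCC(c(1, 2, 3), c(1, 2, 3))    # 1
#' linsCCC(c(-1, 0, 1), c(1, 0, -1))  # -1
#' @export
linsCCC <- function(x, y, sample = FALSE) {
  if (length(x) != length(y))
    stop("x and y must have equal length (", length(x), " vs ", length(y), ")")
  n <- length(x)
  if (n < 3L) stop("at least 3 paired observations are required")
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("x and y must be finite")
  div <- if (sample) n - 1 else n
  mx <- mean(x); my <- mean(y)
  vx <- sum((x - mx)^2) / div
  vy <- sum((y - my)^2) / div
  cxy <- sum((x - mx) * (y - my)) / div
  if (vx == 0 && vy == 0) return(NA_real_)   # no variance on either side
  2 * cxy / (vx + vy + (mx - my)^2)
}

#' Per-feature concordance between two matrix sizes
#'
#' Computes Lin's concordance correlation coefficient for every feature
#' between two [TextureFeatureSet] objects from the same stratum (tissue,
#' mode, normalization) at two different matrix sizes, over the paired
#' subject vectors. Ingredient moments (Pearson correlation, means,
#' standard deviations) are retained for audit. Features that are constant
#' in both tables (or not computable at either size) are flagged undefined
#' and excluded from downstream averages.
#'
#' @param a,b [TextureFeatureSet] objects with identical subjects.
#' @return a [CCCResult-class].
#' @export
cccBetweenMatrices <- function(a, b) {
  stopifnot(is(a, "TextureFeatureSet"), is(b, "TextureFeatureSet"))
  sa <- colnames(a); sb <- colnames(b)
  if (!identical(sa, sb)) {
    diffs <- union(setdiff(sa, sb), setdiff(sb, sa))
    stop("subject sets differ between tables: ",
         paste(diffs, collapse = ", "))
  }
  if (!identical(rownames(a), rownames(b)))
    stop("feature sets differ between tables")
  for (f in c("tissue", "mode", "normalization")) {
    if (!identical(S4Vectors::metadata(a)[[f]], S4Vectors::metadata(b)[[f]]))
      stop("tables come from different strata (", f, " differs)")
  }
  mi <- matrixSize(a); mj <- matrixSize(b)
  if (identical(mi, mj))
    warning("both tables have matrix size ", mi, " (self-pairing)")
  X <- featureValues(a)  # subjects x features
  Y <- featureValues(b)
  n <- nrow(X)
  mux <- colMeans(X); muy <- colMeans(Y)
  # centred moments: exact zeros for constant columns, so degenerate
  # features are reliably flagged undefined
  Xc <- sweep(X, 2, mux); Yc <- sweep(Y, 2, muy)
  vx <- colMeans(Xc^2)
  vy <- colMeans(Yc^2)
  cxy <- colMeans(Xc * Yc)
  den <- vx + vy + (mux - muy)^2
  bad <- !is.finite(den)       # feature not computable at one of the sizes
  degenerate <- !bad & vx == 0 & vy == 0   # constant on both sides
  rho_c <- ifelse(!bad & !degenerate & den > 0, 2 * cxy / den, NA_real_)
  rho <- ifelse(!bad & vx > 0 & vy > 0, cxy / sqrt(vx * vy), NA_real_)
  defined <- is.finite(rho_c)
  tab <- data.frame(
    feature = colnames(X),
    family = featureFamilies(a),
    rho_c = rho_c, rho = rho,
    mu_i = mux, mu_j = muy,
    sigma_i = sqrt(vx), sigma_j = sqrt(vy),
    defined = defined,
    row.names = NULL
  )
  new("CCCResult", table = tab, pair = c(mi, mj),
      tissue = S4Vectors::metadata(a)$tissue,
      mode = S4Vectors::metadata(a)$mode,
      normalization = S4Vectors::metadata(a)$normalization)
}

.pairLabel <- function(p) paste(sort(p), collapse = "-")

#' Aggregate per-feature concordance into a transition report
#'
#' Averages Lin's coefficients per feature family and overall (each defined
#' feature contributing once) for every matrix-size pair in scope:
#' `"neighboring"` uses the one-step transitions (e.g. 256-320, ...,
#' 448-512), `"all_pairs"` every unordered pair. Undefined coefficients are
#' excluded and counted. The report also carries the mean absolute change
#' of the overall average across consecutive neighboring transitions.
#'
#' @param results list of [CCCResult-class] objects from one stratum.
#' @param scope `"neighboring"` or `"all_pairs"`.
#' @param matrixSizes the matrix sizes defining the scope; defaults to the
#'   sizes present in `results`.
#' @return a [TransitionReport-class].
#' @export
aggregateTransitions <- function(results, scope = c("neighboring", "all_pairs"),
                                 matrixSizes = NULL) {
  scope <- match.arg(scope)
  stopifnot(length(results) >= 1L)
  if (is.null(matrixSizes))
    matrixSizes <- sort(unique(unlist(lapply(results, function(r) r@pair))))
  sizes <- sort(as.integer(matrixSizes))
  wanted <- if (scope == "neighboring") {
    lapply(seq_len(length(sizes) - 1L), function(i) sizes[c(i, i + 1L)])
  } else {
    pr <- utils::combn(sizes, 2)
    lapply(seq_len(ncol(pr)), function(i) pr[, i])
  }
  have <- vapply(results, function(r) .pairLabel(r@pair), character(1))
  rows <- list()
  overall <- list()
  for (p in wanted) {
    lbl <- .pairLabel(p)
    idx <- which(have == lbl)
    if (!length(idx)) stop("missing CCC result for matrix pair ", lbl)
    r <- results[[idx[1]]]
    tb <- r@table
    def <- tb$defined & !is.na(tb$rho_c)
    fams <- unique(tb$family)
    famRows <- lapply(c("ALL", fams), function(fm) {
      sel <- if (fm == "ALL") def else def & tb$family == fm
      tot <- if (fm == "ALL") nrow(tb) else sum(tb$family == fm)
      data.frame(tissue = r@tissue, mode = r@mode,
                 normalization = r@normalization, pair = lbl, family = fm,
                 mean_ccc = if (any(sel)) mean(tb$rho_c[sel]) else NA_real_,
                 n_defined = sum(sel), n_excluded = tot - sum(sel))
    })
    rows[[lbl]] <- do.call(rbind, famRows)
    overall[[lbl]] <- rows[[lbl]]$mean_ccc[rows[[lbl]]$family == "ALL"]
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  # mean absolute change of the overall average across consecutive
  # neighboring transitions
  nb <- vapply(seq_len(length(sizes) - 1L),
               function(i) .pairLabel(sizes[c(i, i + 1L)]), character(1))
  nbVals <- unlist(lapply(nb, function(l)
    if (!is.null(overall[[l]])) overall[[l]] else NA_real_))
  mc <- if (sum(is.finite(nbVals)) >= 2L)
    mean(abs(diff(nbVals[is.finite(nbVals)]))) else NA_real_
  r1 <- results[[1]]
  meanChange <- data.frame(tissue = r1@tissue, mode = r1@mode,
                           normalization = r1@normalization,
                           mean_abs_change = mc)
  new("TransitionReport", table = table, meanChange = meanChange,
      scope = scope)
}
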