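# Variance stabilization of sampled vectors and of the whole field via
# negative-binomial Pearson residuals with kernel-regularized per-gene
# parameters, in the style of regularized NB regression for UMI counts.
#
# KDE field values are continuous; they are converted to surrogate
# molecule counts by dividing by the height of a single kernel (so one
# isolated mRNA contributes ~1) and treated as continuous observations
# in the NB quasi-likelihood.

#' Fit the variance-stabilization model
#'
#' For every gene, fits `mu_i = exp(b0 + b1 * log10(m_i))`, where `m_i`
#' is vector `i`'s total surrogate count, by quasi-Poisson regression,
#' then estimates the NB dispersion `theta` by maximum likelihood with
#' the fitted means held fixed. The three parameters are finally
#' regularized across genes by Gaussian kernel regression on
#' `log10(gene mean)`.
#'
#' @param x A `sample_matrix` of raw sampled vectors, or a numeric
#'   n x genes matrix of counts (with column names).
#' @param scale Value of one molecule in the units of `x`; defaults to
#'   the single-kernel height for a `sample_matrix` (see
#'   [kernel_height()]) and 1 for a plain count matrix.
#' @param clip Residual clip bound; default `sqrt(n)`.
#' @param totals Optional per-vector totals to use as covariate in
#'   place of the row sums (e.g. a known sampling-depth covariate).
#' @return A `vst_model` with raw and regularized parameters per gene.
#'   Genes with all-zero or constant values are excluded with a warning
#'   (their residuals are defined as 0 downstream).
#' @export
fit_vst_model <- function(x, scale = NULL, clip = NULL, totals = NULL) {
  if (inherits(x, "sample_matrix")) {
    if (isTRUE(x$normalized)) stop("samples are already normalized")
    scale <- scale %||% kernel_height(x$bandwidth_um, x$dim)
    mat <- x$vectors
  } else {
    mat <- as.matrix(x)
    scale <- scale %||% 1
  }
  if (is.null(colnames(mat))) stop("input needs gene column names")
  n <- nrow(mat)
  if (n < 30L) stop("need at least 30 sampled vectors to fit the model")
  if (ncol(mat) < 2L) stop("need at least 2 genes")
  y <- mat / scale
  m <- totals %||% rowSums(y)
  if (length(m) != nrow(y)) stop("totals length must match the vector count")
  if (any(m <= 0)) {
    warning(sprintf("dropping %d all-zero vector(s) from the fit", sum(m <= 0)))
    y <- y[m > 0, , drop = FALSE]
    m <- m[m > 0]
    n <- nrow(y)
  }
  u <- log10(m)
  usable <- apply(y, 2, function(v) any(v > 0) && stats::sd(v) > 0)
  if (!all(usable))
    warning(sprintf("excluding %d degenerate gene(s) from the model: %s",
                    sum(!usable),
                    paste(colnames(y)[!usable], collapse = ", ")))
  genes <- colnames(y)[usable]
  fit_one <- function(v) {
    co <- tryCatch(
      stats::coef(stats::glm(v ~ u, family = stats::quasipoisson())),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(co) || any(!is.finite(co)))
      co <- c(log(mean(v)), 0)
    mu <- exp(co[1] + co[2] * u)
    theta <- ml_theta(v, mu)
    c(b0 = unname(co[1]), b1 = unname(co[2]), theta = theta)
  }
  pars <- vapply(genes, function(g) fit_one(y[, g]), numeric(3))
  gene_mean <- colMeans(y[, genes, drop = FALSE])
  lx <- log10(gene_mean)
  b0 <- smooth_gaussian(lx, pars["b0", ])
  b1 <- smooth_gaussian(lx, pars["b1", ])
  theta <- 10^smooth_gaussian(lx, log10(pars["theta", ]))
  theta <- pmax(theta, 1e-4)
  structure(list(genes = genes, beta0 = b0, beta1 = b1, theta = theta,
                 beta0_raw = pars["b0", ], beta1_raw = pars["b1", ],
                 theta_raw = pars["theta", ], gene_mean = gene_mean,
                 scale = scale, clip = clip %||% sqrt(n), n = n),
            class = "vst_model")
}

# Continuous-y NB log-likelihood in theta, fitted means fixed.
ml_theta <- function(y, mu, theta_max = 1e6) {
  nll <- function(lt) {
    th <- exp(lt)
    -sum(lgamma(y + th) - lgamma(th) + th * log(th / (th + mu)) +
           y * log(pmax(mu, 1e-12) / (th + mu)))
  }
  opt <- stats::optimize(nll, interval = log(c(1e-3, theta_max)))
  min(exp(opt$minimum), theta_max)
}

# Regularize per-gene parameters across genes as a function of
# log10(gene mean): a robust (Theil-Sen) linear trend plus a Gaussian
# kernel smooth of the deviations from it, with a widened bandwidth
# (3x Silverman, the widened default of regularized NB normalization
# for UMI counts). The robust line keeps the regularization exact when
# parameters genuinely follow a smooth trend of gene mean, while the
# wide smoothing of deviations ties depth-confounded genes (e.g. the
# markers of a low-mRNA-content cell type, whose per-gene regressions
# would otherwise absorb the type's signature into the fitted means)
# to the population trend.
smooth_gaussian <- function(x, p, bw = NULL, outlier_mads = 3) {
  bw <- bw %||% max(3 * stats::bw.nrd0(x), 1e-3)
  trend <- robust_trend(x, p)
  resid <- p - trend
  # genes whose raw estimate falls far off the cross-gene trend are
  # excluded from the regularization and get trend-predicted values
  # (the outlier rule of regularized NB normalization for UMI counts);
  # without it the per-gene regression of a depth-confounded gene
  # absorbs real signal into the fitted mean
  md <- stats::mad(resid)
  out <- if (md > 0) abs(resid) > outlier_mads * md else !is.finite(resid)
  if (all(out)) out[] <- FALSE
  sm <- vapply(x, function(x0) {
    w <- stats::dnorm((x - x0) / bw) * !out
    sum(w * resid) / sum(w)
  }, numeric(1))
  trend + sm
}

# Robust global linear trend (Theil-Sen: median pairwise slope,
# median intercept). A global line is used deliberately: a coherent
# block of depth-confounded genes can occupy an exclusive region of
# the gene-mean axis, where any local trend would follow the block
# instead of the remaining genes.
robust_trend <- function(x, p) {
  n <- length(x)
  if (n < 2L || stats::sd(x) == 0) return(rep(stats::median(p), n))
  ij <- utils::combn(n, 2L)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  keep <- abs(dx) > 1e-12
  if (!any(keep)) return(rep(stats::median(p), n))
  slope <- stats::median((p[ij[2, ]] - p[ij[1, ]])[keep] / dx[keep])
  intercept <- stats::median(p - slope * x)
  intercept + slope * x
}

#' @export
print.vst_model <- function(x, ...) {
  cat(sprintf("vst_model: %d genes fitted on %d vectors (clip %.2f)\n",
              length(x$genes), x$n, x$clip))
  invisible(x)
}

#' Negative-binomial Pearson residual
#'
#' `(x - mu) / sqrt(mu + mu^2/theta)`, clipped to `[-clip, clip]`.
#'
#' @param x Observed (surrogate) count.
#' @param mu Fitted mean.
#' @param theta NB dispersion.
#' @param clip Symmetric clip bound (default: no clipping).
#' @return The clipped residual.
#' @export
pearson_residual <- function(x, mu, theta, clip = Inf) {
  r <- (x - mu) / sqrt(mu + mu^2 / theta)
  pmin(pmax(r, -clip), clip)
}

#' Transform raw vectors into Pearson residuals
#'
#' Applies the model per entry, with each vector's own total surrogate
#' count as covariate. Genes absent from the model get residual 0.
#'
#' @param model A `vst_model`.
#' @param vectors Numeric n x genes matrix of raw values (same units
#'   the model was fitted on), or a raw `sample_matrix`.
#' @param totals Optional per-vector totals overriding the row sums as
#'   covariate (must match the convention the model was fitted with).
#' @return Residual matrix of the same shape as the input.
#' @export
transform_vectors <- function(model, vectors, totals = NULL) {
  if (inherits(vectors, "sample_matrix")) vectors <- vectors$vectors
  vectors <- as.matrix(vectors)
  if (is.null(colnames(vectors))) stop("vectors need gene column names")
  y <- vectors / model$scale
  m <- totals %||% rowSums(y)
  out <- matrix(0, nrow(y), ncol(y), dimnames = dimnames(vectors))
  live <- m > 0
  if (!any(live)) return(out)
  u <- log10(m[live])
  common <- intersect(colnames(vectors), model$genes)
  for (g in common) {
    i <- match(g, model$genes)
    mu <- exp(model$beta0[i] + model$beta1[i] * u)
    out[live, g] <- pearson_residual(y[live, g], mu, model$theta[i],
                                     model$clip)
  }
  out
}

#' Normalize the sampled vectors of a `sample_matrix`
#'
#' @param model A `vst_model`.
#' @param samples A raw `sample_matrix`.
#' @return The `sample_matrix` with `vectors` replaced by residuals and
#'   `normalized = TRUE`.
#' @export
normalize_samples <- function(model, samples) {
  if (isTRUE(samples$normalized)) stop("samples are already normalized")
  samples$vectors <- transform_vectors(model, samples$vectors)
  samples$normalized <- TRUE
  samples
}

#' Normalize a whole vector field
#'
#' Every pixel with positive total expression is transformed exactly as
#' [transform_vectors()]; all-zero pixels stay zero and are flagged as
#' background. Normalizing an already-normalized field is an error.
#'
#' @param model A `vst_model` (fitted on sampled vectors of this field).
#' @param field A raw `vector_field` whose genes include the model's.
#' @return The field with residual values, `normalized = TRUE`, and a
#'   logical `background` element marking all-zero pixels.
#' @export
normalize_field <- function(model, field) {
  if (isTRUE(field$normalized)) stop("field is already normalized")
  if (!all(model$genes %in% field$genes))
    stop("model genes must be a subset of the field's genes")
  mat <- field_matrix(field)
  background <- rowSums(mat) == 0
  res <- transform_vectors(model, mat)
  field$values <- array(res, dim = c(field$shape, length(field$genes)))
  field$normalized <- TRUE
  field$background <- array(background, dim = field$shape)
  field
}

#' Simple scaling alternative to the NB residual normalization
#'
#' Per-vector L1 scaling followed by per-gene z-scoring. A debugging
#' escape hatch for isolating clustering behaviour from the variance
#' stabilization model; not used by the default pipeline.
#'
#' @param samples A raw `sample_matrix`.
#' @param field Optional raw `vector_field` to scale with the gene
#'   means/sds derived from the samples.
#' @return List with normalized `samples` (and `field` if given).
#' @export
normalize_l1_zscore <- function(samples, field = NULL) {
  if (isTRUE(samples$normalized)) stop("samples are already normalized")
  v <- samples$vectors
  sc <- v / pmax(rowSums(v), .Machine$double.eps)
  mu <- colMeans(sc)
  sd <- pmax(apply(sc, 2, stats::sd), .Machine$double.eps)
  samples$vectors <- sweep(sweep(sc, 2, mu), 2, sd, "/")
  samples$normalized <- TRUE
  out <- list(samples = samples)
  if (!is.null(field)) {
    if (isTRUE(field$normalized)) stop("field is already normalized")
    mat <- field_matrix(field)
    background <- rowSums(mat) == 0
    fs <- mat / pmax(rowSums(mat), .Machine$double.eps)
    fs <- sweep(sweep(fs, 2, mu), 2, sd, "/")
    fs[background, ] <- 0
    field$values <- array(fs, dim = c(field$shape, length(field$genes)))
    field$normalized <- TRUE
    field$background <- array(background, dim = field$shape)
    out$field <- field
  }
  out
}
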