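#' Logistic ceiling curve
#'
#' `a / (1 + exp(b * (x - c)))`: a decreasing sigmoid for `b > 0`, symmetric
#' about the point `(c, a/2)`, with `b` the steepness at the symmetry point.
#'
#' @param x numeric vector.
#' @param a,b,c curve parameters.
#' @return numeric vector.
#' @export
sigmoid_ceiling <- function(x, a, b, c) a / (1 + exp(b * (x - c)))

# per-genome defense-system count under a category rule
.category_counts <- function(cohort, category, first_line = character(0)) {
  vapply(cohort, function(g) {
    fam <- g$systems$family
    if (category == "all") length(fam)
    else if (category == "first_line") sum(fam %in% first_line)
    else if (category == "accessory") sum(!fam %in% first_line)
    else if (startsWith(category, "family:"))
      sum(fam == sub("^family:", "", category))
    else stop("unknown category: ", category)
  }, integer(1))
}

#' Build a trade-off upper envelope
#'
#' One point per distinct defense-system count x (under the chosen category
#' rule) carrying the maximum trait count among the genomes in that bin and
#' the bin size. Bins with fewer than `min_bin` genomes are dropped.
#'
#' @param cohort a `defensome_cohort`.
#' @param trait trait name (must exist in every genome's `traits`).
#' @param category `"all"`, `"first_line"`, `"accessory"` or
#'   `"family:<name>"`.
#' @param first_line first-line family set (needed for the partition-based
#'   categories).
#' @param min_bin minimum genomes per bin.
#' @return data frame of class `tradeoff_envelope` (x, y_max, n_at_x).
#' @export
build_envelope <- function(cohort, trait = "ARG", category = "all",
                           first_line = character(0), min_bin = 1L) {
  y <- vapply(cohort, function(g) {
    if (!trait %in% names(g$traits))
      stop("trait ", trait, " missing for genome ", g$qc$genome_id)
    as.numeric(g$traits[[trait]])
  }, numeric(1))
  x <- .category_counts(cohort, category, first_line)
  agg <- split(y, x)
  env <- data.frame(x = as.integer(names(agg)),
                    y_max = vapply(agg, max, numeric(1)),
                    n_at_x = lengths(agg), row.names = NULL)
  env <- env[env$n_at_x >= min_bin, , drop = FALSE]
  env <- env[order(env$x), ]
  rownames(env) <- NULL
  if (!nrow(env)) stop("empty envelope")
  structure(env, class = c("tradeoff_envelope", "data.frame"),
            trait = trait, category = category)
}

#' Fit the logistic ceiling to an envelope by multi-start least squares
#'
#' Minimises the envelope sum of squares over (a, b, c) with
#' Levenberg-Marquardt local fits from a deterministic grid of starts
#' (a0 = max(y), c0 spread over the x range, b0 in {+-0.1, +-1}) topped up
#' with seeded jittered starts; the best converged fit by SSE wins. R^2 is
#' computed on the envelope points as 1 - SSE / SST.
#'
#' @param env a `tradeoff_envelope` (or data frame with x, y_max).
#' @param n_starts total number of starts.
#' @param seed seed for the jittered starts.
#' @return list of class `sigmoid_fit`: a, b, c, r_squared, sse, converged,
#'   n_points, seed.
#' @export
fit_sigmoid <- function(env, n_starts = 16L, seed = 1L) {
  x <- env$x; y <- env$y_max
  if (length(x) < 4) stop("need at least 4 envelope points")
  fail <- function() structure(list(a = NA_real_, b = NA_real_, c = NA_real_,
                                    r_squared = NA_real_, sse = NA_real_,
                                    converged = FALSE,
                                    n_points = length(x), seed = seed),
                               class = "sigmoid_fit")
  if (stats::sd(y) == 0) return(fail()) # b unidentifiable on a flat envelope
  a0 <- max(y)
  c_grid <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  b_grid <- c(0.1, -0.1, 1, -1)
  starts <- expand.grid(a = a0, b = b_grid, c = c_grid)
  extra <- n_starts - nrow(starts)
  if (extra > 0) {
    jit <- .with_seed(seed, data.frame(
      a = a0 * stats::runif(extra, 0.5, 1.5),
      b = stats::runif(extra, -2, 2),
      c = stats::runif(extra, min(x), max(x))))
    starts <- rbind(starts, jit)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a / (1 + exp(b * (x - c))),
                        start = as.list(starts[i, ]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::resid(fit)^2)
    if (is.null(best) || sse < best$sse)
      best <- list(coef = stats::coef(fit), sse = sse)
  }
  if (is.null(best)) return(fail())
  cf <- best$coef
  structure(list(a = unname(cf["a"]), b = unname(cf["b"]), c = unname(cf["c"]),
                 r_squared = r_squared(y, sigmoid_ceiling(x, cf["a"], cf["b"],
                                                          cf["c"])),
                 sse = best$sse, converged = TRUE, n_points = length(x),
                 seed = seed),
            class = "sigmoid_fit")
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<sigmoid_fit> a=%.4g b=%.4g c=%.4g R2=%.4f (n=%d)\n",
                x$a, x$b, x$c, x$r_squared, x$n_points))
  else cat("<sigmoid_fit> not converged\n")
  invisible(x)
}

#' Coefficient of determination
#'
#' `1 - sum((y_obs - y_fit)^2) / sum((y_obs - mean(y_obs))^2)`.
#'
#' @param y_obs observed values (non-constant).
#' @param y_fit fitted values.
#' @return R^2 as a scalar.
#' @export
r_squared <- function(y_obs, y_fit) {
  if (length(y_obs) != length(y_fit)) stop("length mismatch")
  if (length(y_obs) < 2) stop("need at least 2 points")
  sst <- sum((y_obs - mean(y_obs))^2)
  if (sst == 0) stop("R^2 undefined for constant y_obs")
  1 - sum((y_obs - y_fit)^2) / sst
}

#' Trait-vs-defense correlations per system category
#'
#' Spearman correlation of the per-genome trait count against the per-genome
#' defense-system count under each category rule: all systems, first-line
#' only, accessory only, and each first-line family. Categories with a
#' constant count vector yield NA.
#'
#' @param cohort a `defensome_cohort` (>= 4 genomes).
#' @param trait trait name.
#' @param first_line first-line family set.
#' @return data frame (category, rho, p).
#' @export
category_correlations <- function(cohort, trait = "ARG",
                                  first_line = character(0)) {
  if (length(cohort) < 4) stop("need at least 4 genomes")
  y <- vapply(cohort, function(g) as.numeric(g$traits[[trait]]), numeric(1))
  cats <- c("all", "first_line", "accessory",
            paste0("family:", first_line))
  rows <- lapply(cats, function(ct) {
    x <- .category_counts(cohort, ct, first_line)
    res <- tryCatch(ds_spearman(x, y),
                    error = function(e) list(rho = NA_real_, p = NA_real_))
    data.frame(category = ct, rho = res$rho, p = res$p,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
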