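#' Build a presence/absence matrix from classified families
#'
#' Entry (f, g) counts the members of family f in genome g whose replicon
#' passes the filter.  Rows that become all-zero under a replicon filter
#' are dropped (with a message stating the count); the filter is recorded
#' in the `replicon_filter` attribute.
#'
#' @param families long-format family table ([build_families()]).
#' @param records annotated records carrying `replicon_type`.
#' @param replicon_filter one of `"all"`, `"chromosome"`, `"plasmid"`.
#' @param genome_ids column universe; defaults to the genomes in `records`.
#' @return Integer matrix, families x genomes.
#' @export
build_presence_matrix <- function(families, records,
                                  replicon_filter = c("all", "chromosome",
                                                      "plasmid"),
                                  genome_ids = NULL) {
  replicon_filter <- match.arg(replicon_filter)
  if (is.null(genome_ids)) genome_ids <- sort(unique(records$genome_id))
  rt <- records$replicon_type[match(families$gene_id, records$gene_id)]
  if (anyNA(rt)) stop("family gene(s) absent from records")
  keep <- switch(replicon_filter,
                 all = rep(TRUE, nrow(families)),
                 chromosome = rt == "chromosome",
                 plasmid = rt == "plasmid")
  fam <- families[keep, , drop = FALSE]
  all_fams <- sort(unique(families$family_id))
  tab <- table(factor(fam$family_id, levels = all_fams),
               factor(fam$genome_id, levels = genome_ids))
  mat <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = dimnames(tab))
  empty <- rowSums(mat) == 0L
  if (any(empty))
    message("dropped ", sum(empty), " famil(ies) with no member on ",
            replicon_filter, " replicons")
  mat <- mat[!empty, , drop = FALSE]
  attr(mat, "replicon_filter") <- replicon_filter
  mat
}

all_permutations <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v))
    out <- c(out, lapply(all_permutations(v[-i]), function(p) c(v[i], p)))
  out
}

#' Pan/core accumulation over genome-order permutations
#'
#' For each genome ordering, `pan[k]` is the number of families present in
#' at least one of the first k genomes and `core[k]` the number present in
#' all of them.  When the total number of orderings is at most
#' `exhaustive_limit` (default 5040, i.e. up to 7 genomes), all orderings
#' are enumerated; otherwise `n_permutations` random orderings are sampled.
#'
#' @param mat presence/absence matrix ([build_presence_matrix()]).
#' @param n_permutations number of sampled orderings.
#' @param seed integer seed for the sampled case.
#' @param exhaustive_limit enumerate exhaustively up to this many orderings.
#' @return List of class `pan_curves`: `pan` and `core` (permutation x k
#'   matrices), `orders`, `mean_pan`, `mean_core`, `median_pan`,
#'   `median_core`, `new_genes` (first differences of the mean pan curve),
#'   `exhaustive`.
#' @export
accumulation <- function(mat, n_permutations = 100L, seed = NULL,
                         exhaustive_limit = 5040L) {
  K <- ncol(mat)
  if (K < 2L) stop("need at least two genomes")
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  exhaustive <- factorial(K) <= exhaustive_limit
  if (exhaustive) {
    orders <- all_permutations(seq_len(K))
  } else {
    if (!is.null(seed)) set.seed(seed)
    orders <- replicate(n_permutations, sample.int(K), simplify = FALSE)
  }
  P <- length(orders)
  pres <- mat > 0
  pan <- core <- matrix(0L, P, K)
  for (p in seq_len(P)) {
    un <- rep(FALSE, nrow(mat))
    inall <- rep(TRUE, nrow(mat))
    ord <- orders[[p]]
    for (k in seq_len(K)) {
      un <- un | pres[, ord[k]]
      inall <- inall & pres[, ord[k]]
      pan[p, k] <- sum(un)
      core[p, k] <- sum(inall)
    }
  }
  mean_pan <- colMeans(pan)
  structure(list(pan = pan, core = core, orders = orders,
                 mean_pan = mean_pan, mean_core = colMeans(core),
                 median_pan = apply(pan, 2L, median),
                 median_core = apply(core, 2L, median),
                 new_genes = diff(mean_pan), exhaustive = exhaustive),
            class = "pan_curves")
}

central_curve <- function(curves, what = c("pan", "core"),
                          central = c("mean", "median")) {
  what <- match.arg(what)
  central <- match.arg(central)
  if (inherits(curves, "pan_curves"))
    curves[[paste(central, what, sep = "_")]]
  else
    as.numeric(curves)
}

#' Fit a power law to the pan curve and call the pan-genome open or closed
#'
#' Least-squares fit of `P(n) = a * n^b` to the central (mean) pan curve by
#' linear regression in log-log space.  The pan-genome is called *closed*
#' when the fitted exponent b falls below `threshold` (default 0.5) and
#' *open* otherwise.
#'
#' @param curves a `pan_curves` object or a numeric pan curve.
#' @param threshold exponent threshold for the closed call.
#' @param central use the mean (default) or median curve.
#' @return List `a`, `b`, `verdict` ("open"/"closed"), `threshold`.
#' @export
fit_pan_powerlaw <- function(curves, threshold = 0.5,
                             central = c("mean", "median")) {
  y <- central_curve(curves, "pan", match.arg(central))
  if (length(y) < 3L) stop("pan curve too short to fit")
  if (any(y <= 0)) stop("non-positive pan curve values")
  n <- seq_along(y)
  fit <- lm(log(y) ~ log(n))
  b <- unname(coef(fit)[2L])
  a <- exp(unname(coef(fit)[1L]))
  list(a = a, b = b,
       verdict = if (b < threshold) "closed" else "open",
       threshold = threshold)
}

#' Fit a decaying exponential to the core curve
#'
#' Nonlinear least squares for `C(n) = c * exp(d * n) + k0`, initialized
#' from `(C(1) - C(max), log-slope estimate, C(max))`; `k0` estimates the
#' asymptotic core-genome size.  An exactly constant curve is returned as
#' the degenerate fit `(c = 0, d = 0, k0 = mean)`.
#'
#' @param curves a `pan_curves` object or a numeric core curve.
#' @param central use the mean (default) or median curve.
#' @return List `c`, `d`, `k0`.
#' @export
fit_core_exponential <- function(curves, central = c("mean", "median")) {
  y <- central_curve(curves, "core", match.arg(central))
  if (length(y) < 4L) stop("core curve too short to fit")
  n <- seq_along(y)
  K <- length(y)
  if (diff(range(y)) < 1e-10 * max(abs(y), 1))
    return(list(c = 0, d = 0, k0 = mean(y)))
  k0_0 <- y[K]
  c_0 <- y[1L] - y[K]
  resid1 <- y[1L] - k0_0
  resid2 <- y[2L] - k0_0
  d_0 <- if (resid1 > 0 && resid2 > 0) log(resid2 / resid1) else -0.5
  if (!is.finite(d_0) || d_0 >= 0) d_0 <- -0.5
  start <- list(c = c_0 / exp(d_0), d = d_0, k0 = k0_0)
  fit <- tryCatch(
    nls(y ~ c * exp(d * n) + k0, start = start,
        control = list(maxiter = 500, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ c * exp(d * n) + k0, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e)
        stop("core exponential fit failed; start = (",
             paste(signif(unlist(start), 4), collapse = ", "),
             "), curve range = (", paste(range(y), collapse = ", "), ")"))
  cf <- coef(fit)
  list(c = unname(cf["c"]), d = unname(cf["d"]), k0 = unname(cf["k0"]))
}

#' Mean number of new genes per added genome
#'
#' Average of the new-gene increments of the central pan curve over
#' iterations 2 .. `first_k + 1` (i.e. the first `first_k` genome
#' additions).
#'
#' @param curves a `pan_curves` object or numeric pan curve.
#' @param first_k window size in genome additions.
#' @param central mean (default) or median curve.
#' @return Mean new genes per genome over the window.
#' @export
new_gene_rate <- function(curves, first_k, central = c("mean", "median")) {
  y <- central_curve(curves, "pan", match.arg(central))
  if (first_k >= length(y))
    stop("window exceeds curve length")
  mean(diff(y)[seq_len(first_k)])
}
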