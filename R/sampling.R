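# Artificial-centering hit-and-run (ACHR) sampling of the flux polytope
# {v : S v = 0, lb <= v <= ub}. Directions are differences between stored
# points and their running center, projected onto the null space of the
# equality constraints; every kept point is revalidated against S v = 0 and
# the bounds.

#' Sample the flux polytope
#'
#' Seed-deterministic artificial-centering hit-and-run over the feasible
#' set of a (constrained) model. Warm-up points are the flux-variability
#' vertices (per-reaction min/max LPs), which also expose numerically
#' determined fluxes; the chain is thinned and periodically reprojected
#' onto the equality subspace to keep `S v = 0` within tolerance.
#'
#' @param model A feasible `metabolic_model` (constrain first via
#'   [apply_condition()]).
#' @param n Number of samples to keep (>= 1).
#' @param seed Integer RNG seed; same seed and model give bitwise-identical
#'   output.
#' @param thinning Keep every `thinning`-th chain point (default 100).
#' @param n_warmup Optional cap on the number of warm-up vertices kept
#'   (default: all flux-variability vertices).
#' @param tol Validation tolerance on `S v = 0` and the bounds (1e-6).
#' @return A `sampling_result`: list with `samples` (`n` x reactions
#'   matrix), `reaction_ids`, `seed`, `n_kept`, `thinning`.
#' @export
sample_fluxes <- function(model, n, seed, thinning = 100, n_warmup = NULL,
                          tol = 1e-6) {
  stopifnot(n >= 1)
  set.seed(seed)
  nr <- n_reactions(model)
  lb <- pmax(model$reactions$lower_bound, -.LP_BIG)
  ub <- pmin(model$reactions$upper_bound, .LP_BIG)
  S <- as.matrix(model$S)

  # treat (near-)fixed variables as equalities so the null space excludes them
  fixed <- (ub - lb) < 1e-9
  A <- S
  b <- rep(0, nrow(S))
  if (any(fixed)) {
    E <- matrix(0, sum(fixed), nr)
    E[cbind(seq_len(sum(fixed)), which(fixed))] <- 1
    A <- rbind(S, E)
    b <- c(b, (lb[fixed] + ub[fixed]) / 2)
  }
  sv <- svd(A, nv = ncol(A))  # full V: the null space lives in columns rk+1..n
  rk <- sum(sv$d > max(dim(A)) * max(sv$d, 0) * 1e-12)
  N <- sv$v[, -seq_len(rk), drop = FALSE]        # orthonormal null basis
  if (ncol(N) == 0) {
    # zero-dimensional polytope: the unique point, if feasible
    x <- qr.solve(A, b)
    if (max(abs(A %*% x - b)) > tol ||
        any(x < lb - tol) || any(x > ub + tol)) {
      stop("model is infeasible; nothing to sample")
    }
    samples <- matrix(rep(pmin(pmax(x, lb), ub), each = n), nrow = n,
                      dimnames = list(NULL, model$reactions$id))
    return(structure(list(samples = samples,
                          reaction_ids = model$reactions$id, seed = seed,
                          n_kept = n, thinning = thinning),
                     class = "sampling_result"))
  }
  project_eq <- function(x) {
    # exact reprojection onto {A x = b} (minimum-norm correction)
    r <- drop(A %*% x) - b
    x - drop(sv$v[, seq_len(rk), drop = FALSE] %*%
               ((crossprod(sv$u[, seq_len(rk), drop = FALSE], r)) / sv$d[seq_len(rk)]))
  }

  # flux-variability warm-up: min/max each free flux; the optima are
  # well-spread vertices and the ranges expose fluxes that are numerically
  # determined (zero-width) despite lying in the null space
  free_idx <- which(!fixed)
  warm_list <- list()
  fva_lo <- lb; fva_hi <- ub
  for (j in free_idx) {
    obj <- numeric(nr); obj[j] <- 1
    for (maximize in c(TRUE, FALSE)) {
      res <- solve_lp(S, rep(0, nrow(S)), lb, ub, obj, maximize = maximize)
      if (res$status == "infeasible") {
        stop("model is infeasible; nothing to sample")
      }
      if (res$status != "optimal") next
      if (maximize) fva_hi[j] <- res$x[j] else fva_lo[j] <- res$x[j]
      warm_list[[length(warm_list) + 1L]] <- res$x
    }
  }
  if (length(warm_list) < 2L) {
    stop("could not generate warm-up points (solver failures)")
  }
  determined <- fva_hi - fva_lo < 1e-9
  if (all(determined)) {
    x <- project_eq(warm_list[[1L]])
    samples <- matrix(rep(pmin(pmax(x, lb), ub), each = n), nrow = n,
                      dimnames = list(NULL, model$reactions$id))
    return(structure(list(samples = samples,
                          reaction_ids = model$reactions$id, seed = seed,
                          n_kept = n, thinning = thinning),
                     class = "sampling_result"))
  }
  fixed <- fixed | determined   # never move determined coordinates
  warm <- do.call(rbind, warm_list)
  if (!is.null(n_warmup) && nrow(warm) > n_warmup) {
    warm <- warm[round(seq(1L, nrow(warm), length.out = n_warmup)), ,
                 drop = FALSE]
  }
  warm <- t(apply(warm, 1L, project_eq))

  # classic ACHR: directions from the static warm-up set minus a running
  # center over all accepted points; the chain itself stays on the equality
  # subspace by periodic exact reprojection
  center <- project_eq(colMeans(warm))
  npts <- nrow(warm)
  x <- center
  samples <- matrix(NA_real_, n, nr,
                    dimnames = list(NULL, model$reactions$id))
  kept <- 0L; step <- 0L; total_pts <- npts
  max_steps <- 1000L * n * max(thinning, 1L)
  while (kept < n) {
    step <- step + 1L
    if (step > max_steps) stop("sampler failed to advance (degenerate polytope?)")
    ref <- warm[sample.int(npts, 1L), ]
    d <- ref - center
    d[fixed] <- 0           # fixed fluxes never move (float noise otherwise)
    nd <- sqrt(sum(d * d))
    if (nd < 1e-9) next
    d <- d / nd
    act <- which(d != 0)
    if (length(act) == 0) next
    lo_t <- (lb[act] - x[act]) / d[act]
    hi_t <- (ub[act] - x[act]) / d[act]
    tmin <- max(pmin(lo_t, hi_t)); tmax <- min(pmax(lo_t, hi_t))
    if (!is.finite(tmin) || !is.finite(tmax) || tmax - tmin < 1e-12) next
    x <- x + stats::runif(1, tmin, tmax) * d
    if (step %% 25L == 0L) x <- project_eq(x)
    # running center over all accepted points (artificial centering)
    total_pts <- total_pts + 1L
    center <- center + (x - center) / total_pts
    if (step %% thinning == 0L) {
      xs <- project_eq(x)
      xs <- pmin(pmax(xs, lb), ub)
      kept <- kept + 1L
      samples[kept, ] <- xs
    }
  }
  resid <- apply(abs(samples %*% t(S)), 1, max)
  viol <- pmax(
    apply(sweep(samples, 2, lb, "-"), 1, function(z) max(0, -min(z))),
    apply(sweep(samples, 2, ub, "-"), 1, function(z) max(0, max(z))))
  if (any(resid > tol) || any(viol > tol)) {
    stop("internal error: sampler produced points violating constraints ",
         "(max |S v| = ", signif(max(resid), 3),
         ", max bound violation = ", signif(max(viol), 3), ")")
  }
  structure(list(samples = samples, reaction_ids = model$reactions$id,
                 seed = seed, n_kept = n, thinning = thinning),
            class = "sampling_result")
}

#' @export
print.sampling_result <- function(x, ...) {
  cat("<sampling_result> ", x$n_kept, " samples x ",
      length(x$reaction_ids), " reactions (seed ", x$seed,
      ", thinning ", x$thinning, ")\n", sep = "")
  invisible(x)
}

#' Mean and sd production rates from a sampling result
#'
#' Summarizes exchange fluxes with a production-positive sign convention:
#' an exchange written `met_e ->` carries coefficient -1, so its raw flux is
#' already positive for export; reactions written the other way round are
#' flipped.
#'
#' @param sr A [sample_fluxes()] result.
#' @param exchange_ids Character vector of exchange reaction ids.
#' @param model Optional model; when given, the sign convention is derived
#'   from each exchange's stoichiometry and metabolite names are attached.
#' @return `data.frame` with `reaction_id`, `metabolite`, `mean`, `sd`
#'   (mmol h^-1, production-positive).
#' @export
product_profile <- function(sr, exchange_ids, model = NULL) {
  missing_ids <- setdiff(exchange_ids, sr$reaction_ids)
  if (length(missing_ids)) stop("unknown reaction id: ", missing_ids[1])
  out <- data.frame(reaction_id = exchange_ids,
                    metabolite = NA_character_,
                    mean = NA_real_, sd = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(exchange_ids)) {
    v <- sr$samples[, exchange_ids[i]]
    sgn <- 1
    if (!is.null(model) && exchange_ids[i] %in% model$reactions$id) {
      st <- reaction_stoichiometry(model, exchange_ids[i])
      if (length(st) == 1) {
        out$metabolite[i] <- names(st)
        sgn <- -sign(st[[1]])
      }
    }
    out$mean[i] <- mean(sgn * v)
    out$sd[i] <- stats::sd(sgn * v)
  }
  out
}
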