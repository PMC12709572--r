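#' Assemble an EEM cube from per-sample matrices
#'
#' Stacks EEMs sharing a common excitation/emission grid into a three-way
#' array (sample x ex x em) with a shared cell mask, the substrate for
#' [fit_parafac()]. Masks of the individual EEMs are OR-combined: a cell
#' excised anywhere is excised for all samples, which keeps the masked
#' least-squares problem identical across slabs.
#'
#' @param eems named list of [eem()] objects with identical grids.
#' @return An object of class `eem_cube`: list with `sample_ids`, `ex_nm`,
#'   `em_nm`, `tensor` (array), `mask` (ex x em logical).
#' @export
eem_cube <- function(eems) {
  stopifnot(length(eems) >= 1)
  ex <- eems[[1]]$ex_nm; em <- eems[[1]]$em_nm
  for (e in eems) {
    if (!isTRUE(all.equal(e$ex_nm, ex)) || !isTRUE(all.equal(e$em_nm, em))) {
      abort("all EEMs in a cube must share excitation and emission grids")
    }
  }
  ids <- names(eems) %||% paste0("S", seq_along(eems))
  tensor <- array(0, dim = c(length(eems), length(ex), length(em)))
  mask <- matrix(FALSE, length(ex), length(em))
  for (i in seq_along(eems)) {
    tensor[i, , ] <- eems[[i]]$intensity
    mask <- mask | eems[[i]]$mask
  }
  structure(list(sample_ids = ids, ex_nm = ex, em_nm = em,
                 tensor = tensor, mask = mask),
            class = "eem_cube")
}

#' @export
print.eem_cube <- function(x, ...) {
  d <- dim(x$tensor)
  cat("<eem_cube> ", d[1], " samples x ", d[2], " ex x ", d[3], " em; ",
      sum(x$mask), " masked cells per slab\n", sep = "")
  invisible(x)
}

#' Mask Rayleigh scatter ridges in an EEM cube
#'
#' Masks every cell within `first_order_halfwidth` nm of the em = ex line and
#' within `second_order_halfwidth` nm of the em = 2 ex line. Intensities are
#' left untouched; masked cells are simply excluded from downstream fitting.
#'
#' @param cube an [eem_cube()] (or single [eem()]).
#' @param first_order_halfwidth,second_order_halfwidth half-widths in nm
#'   (>= 0); a half-width of 0 masks only cells exactly on the ridge line.
#' @return The cube with an enlarged mask.
#' @export
excise_scatter <- function(cube, first_order_halfwidth = 15,
                           second_order_halfwidth = 15) {
  if (first_order_halfwidth < 0 || second_order_halfwidth < 0) {
    abort("halfwidths must be >= 0")
  }
  ex <- if (inherits(cube, "eem")) cube$ex_nm else cube$ex_nm
  em <- cube$em_nm
  ridge <- outer(ex, em, function(x, m) abs(m - x) <= first_order_halfwidth) |
    outer(ex, em, function(x, m) abs(m - 2 * x) <= second_order_halfwidth)
  cube$mask <- cube$mask | ridge
  cube
}

# Fast non-negative least squares on precomputed normal equations
# (active-set method of Bro & de Jong 1997). Solves min ||Zx - b||, x >= 0
# given ZtZ and Ztb.
fnnls <- function(ZtZ, Ztb, eps = .Machine$double.eps * 100) {
  n <- length(Ztb)
  x <- numeric(n)
  passive <- logical(n)
  w <- Ztb - ZtZ %*% x
  tol <- eps * max(abs(ZtZ)) * n
  iter <- 0; max_iter <- 30 * n
  while (any(!passive) && any(w[!passive] > tol) && iter < max_iter) {
    iter <- iter + 1
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      s <- numeric(n)
      p <- which(passive)
      sol <- tryCatch(solve(ZtZ[p, p, drop = FALSE], Ztb[p]),
                      error = function(e) NULL)
      if (is.null(sol)) {
        sol <- qr.coef(qr(ZtZ[p, p, drop = FALSE]), Ztb[p])
        sol[is.na(sol)] <- 0
      }
      s[p] <- sol
      if (all(s[p] > tol)) { x <- s; break }
      q <- p[s[p] <= tol]
      alpha <- min(x[q] / (x[q] - s[q] + .Machine$double.xmin))
      x <- x + alpha * (s - x)
      x[x < tol] <- 0
      passive <- passive & x > 0
      if (!any(passive)) { x[] <- 0; break }
    }
    w <- Ztb - ZtZ %*% x
  }
  pmax(x, 0)
}

#' Non-negative PARAFAC decomposition of an EEM cube
#'
#' Fits the trilinear model \eqn{x_{nij} \approx \sum_f a_{nf} b_{if} c_{jf}}
#' by alternating non-negative least squares in all three modes, ignoring
#' masked cells in the objective. The best of `n_restarts` random
#' non-negative initializations (by final masked SSE) is returned. Excitation
#' and emission loadings are normalized to unit maximum with the scale
#' absorbed into the sample scores, and components are ordered by explained
#' sum of squares.
#'
#' @param cube an [eem_cube()].
#' @param n_components model rank (>= 1, <= number of samples).
#' @param n_restarts random restarts (default 10).
#' @param tol relative SSE change declaring convergence (default 1e-8).
#' @param max_iter ALS iteration cap per restart; reaching it returns the
#'   model with `converged = FALSE` and a warning.
#' @param seed integer seed; restart r uses a seed derived from (seed, r).
#' @return An object of class `parafac`: list with `scores` (sample x f),
#'   `ex_loadings`, `em_loadings`, `n_components`, `explained_variance`,
#'   `sse`, `sse_history` (of the winning restart), `iterations`,
#'   `converged`, `labels` (NULL until [match_components()]), plus the grids
#'   and sample ids.
#' @export
fit_parafac <- function(cube, n_components = 6L, n_restarts = 10L,
                        tol = 1e-8, max_iter = 2000L, seed = 1L) {
  stopifnot(inherits(cube, "eem_cube"))
  n <- dim(cube$tensor)[1]
  if (n_components < 1) abort("n_components must be >= 1")
  if (n < n_components) abort("cube must have at least n_components samples")

  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- parafac_als(cube$tensor, cube$mask, n_components, tol, max_iter,
                       derive_seed(seed, paste0("parafac_restart_", r)))
    if (is.null(best) || fit$sse < best$sse) best <- fit
  }
  if (!best$converged) {
    warn("PARAFAC ALS reached max_iter without meeting tol")
  }

  # normalize loadings to unit max, absorb scale into scores
  A <- best$A; B <- best$B; C <- best$C
  for (f in seq_len(n_components)) {
    bmax <- max(B[, f]); cmax <- max(C[, f])
    if (bmax > 0) { B[, f] <- B[, f] / bmax } else bmax <- 1
    if (cmax > 0) { C[, f] <- C[, f] / cmax } else cmax <- 1
    A[, f] <- A[, f] * bmax * cmax
  }
  # order components by explained sum of squares
  energy <- vapply(seq_len(n_components), function(f) {
    sum(A[, f]^2) * sum(B[, f]^2) * sum(C[, f]^2)
  }, numeric(1))
  ord <- order(energy, decreasing = TRUE)
  A <- A[, ord, drop = FALSE]
  B <- B[, ord, drop = FALSE]
  C <- C[, ord, drop = FALSE]

  sst <- sum(sweep_mask(cube$tensor, cube$mask)^2)
  structure(list(
    scores = A, ex_loadings = B, em_loadings = C,
    n_components = as.integer(n_components),
    explained_variance = if (sst > 0) 1 - best$sse / sst else NA_real_,
    sse = best$sse, sse_history = best$sse_history,
    iterations = best$iterations, converged = best$converged,
    labels = NULL, match_congruence = NULL,
    sample_ids = cube$sample_ids, ex_nm = cube$ex_nm, em_nm = cube$em_nm,
    mask = cube$mask, seed = as.integer(seed)
  ), class = "parafac")
}

# zero out masked cells of every slab
sweep_mask <- function(tensor, mask) {
  n <- dim(tensor)[1]
  keep <- !mask
  for (i in seq_len(n)) tensor[i, , ] <- tensor[i, , ] * keep
  tensor
}

# column-wise Khatri-Rao product with the rows of `small` cycling fastest
khatri_rao <- function(big, small) {
  nb <- nrow(big); ns <- nrow(small)
  small[rep(seq_len(ns), times = nb), , drop = FALSE] *
    big[rep(seq_len(nb), each = ns), , drop = FALSE]
}

# ALS sweep engine. Masked cells are excluded from the reported objective;
# numerically they are completed with the current model before each sweep
# (majorization), which monotonically decreases the masked SSE while keeping
# every mode update a dense matricized product.
parafac_als <- function(X, mask, F_, tol, max_iter, seed) {
  n <- dim(X)[1]; I <- dim(X)[2]; J <- dim(X)[3]
  keepvec <- as.vector(!mask)              # length I*J, shared across samples
  anymask <- any(mask)

  X1 <- matrix(X, n, I * J)                # mode-1 unfolding, ex fastest
  X1[, !keepvec] <- 0
  sst <- sum(X1^2)
  tiny <- max(sst, 1e-300)

  to_unfoldings <- function(X1c) {
    arr <- array(X1c, dim = c(n, I, J))
    list(X2 = matrix(aperm(arr, c(2, 1, 3)), I, n * J),
         X3 = matrix(aperm(arr, c(3, 1, 2)), J, n * I))
  }

  set.seed(seed)
  A <- matrix(abs(rnorm(n * F_)), n, F_)
  B <- matrix(abs(rnorm(I * F_)), I, F_)
  C <- matrix(abs(rnorm(J * F_)), J, F_)

  # solve all rows unconstrained in one shot; rows violating non-negativity
  # are re-solved with the active-set NNLS
  nnls_rows <- function(ZtZ, V) {
    scale <- max(diag(ZtZ), 0)
    neg_tol <- -1e-10 * max(scale, 1e-300)
    sol <- tryCatch(t(solve(ZtZ, t(V))), error = function(e) NULL)
    if (is.null(sol)) {
      sol <- matrix(0, nrow(V), ncol(V))
      for (r in seq_len(nrow(V))) sol[r, ] <- fnnls(ZtZ, V[r, ])
      return(sol)
    }
    bad <- which(apply(sol, 1, min) < neg_tol)
    for (r in bad) sol[r, ] <- fnnls(ZtZ, V[r, ])
    sol[sol < 0] <- 0
    sol
  }

  X1c <- X1
  if (!anymask) unf <- to_unfoldings(X1)
  sse_prev <- Inf
  sse_history <- numeric(0)
  converged <- FALSE
  it <- 0
  Xhat1 <- NULL
  while (it < max_iter) {
    it <- it + 1

    if (anymask) {
      if (!is.null(Xhat1)) X1c[, !keepvec] <- Xhat1[, !keepvec]
      unf <- to_unfoldings(X1c)
    }

    A <- nnls_rows(crossprod(B) * crossprod(C),
                   X1c %*% khatri_rao(C, B))
    B <- nnls_rows(crossprod(A) * crossprod(C),
                   unf$X2 %*% khatri_rao(C, A))
    C <- nnls_rows(crossprod(A) * crossprod(B),
                   unf$X3 %*% khatri_rao(B, A))

    # rebalance column scales for numerical stability
    for (f in seq_len(F_)) {
      nb <- sqrt(sum(B[, f]^2)); nc <- sqrt(sum(C[, f]^2))
      if (nb > 0 && nc > 0) {
        B[, f] <- B[, f] / nb; C[, f] <- C[, f] / nc
        A[, f] <- A[, f] * nb * nc
      }
    }

    Xhat1 <- A %*% t(khatri_rao(C, B))
    res <- X1 - Xhat1
    if (anymask) res[, !keepvec] <- 0
    sse <- sum(res^2)
    sse_history <- c(sse_history, sse)
    if (is.finite(sse_prev)) {
      if (abs(sse_prev - sse) / max(sse_prev, tiny * 1e-12) < tol ||
          sse / tiny < 1e-14) {
        converged <- TRUE
        break
      }
    }
    sse_prev <- sse
  }
  list(A = A, B = B, C = C, sse = sse_history[length(sse_history)],
       sse_history = sse_history, iterations = it, converged = converged)
}

#' @export
print.parafac <- function(x, ...) {
  cat("<parafac> ", x$n_components, " components, ",
      length(x$sample_ids), " samples\n", sep = "")
  cat("  explained variance ", signif(100 * x$explained_variance, 4),
      "%; ", x$iterations, " iterations; converged: ", x$converged, "\n",
      sep = "")
  if (!is.null(x$labels)) {
    cat("  labels: ", paste(x$labels, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Core consistency diagnostic (CORCONDIA)
#'
#' Measures how well the fitted factors support a trilinear (superdiagonal
#' core) model: 100 for perfect trilinearity, lower (possibly negative) when
#' the model over-factors the data. The least-squares Tucker core is computed
#' from the fitted loadings on the mask-completed tensor (masked cells filled
#' with the model reconstruction, which leaves the diagnostic driven by the
#' observed cells).
#'
#' @param model a [fit_parafac()] model.
#' @param cube the [eem_cube()] the model was fitted on.
#' @return The CORCONDIA score (percent, <= 100), or `NA` with a warning for
#'   degenerate (zero) loadings.
#' @export
core_consistency <- function(model, cube) {
  A <- model$scores; B <- model$ex_loadings; C <- model$em_loadings
  F_ <- model$n_components
  if (any(colSums(A) == 0) || any(colSums(B) == 0) || any(colSums(C) == 0)) {
    warn("core consistency undefined: degenerate zero loadings")
    return(NA_real_)
  }
  X <- cube$tensor
  n <- dim(X)[1]
  # fill masked cells with the model reconstruction
  if (any(cube$mask)) {
    for (i in seq_len(n)) {
      fit <- B %*% t(C * rep(A[i, ], each = nrow(C)))
      slab <- X[i, , ]
      slab[cube$mask] <- fit[cube$mask]
      X[i, , ] <- slab
    }
  }
  pinv <- function(M) {
    s <- svd(M)
    pos <- s$d > max(dim(M)) * .Machine$double.eps * s$d[1]
    s$v[, pos, drop = FALSE] %*%
      (t(s$u[, pos, drop = FALSE]) / s$d[pos])
  }
  # Tucker core G = X x1 A+ x2 B+ x3 C+
  Ai <- pinv(A); Bi <- pinv(B); Ci <- pinv(C)
  X1 <- matrix(X, n, dim(X)[2] * dim(X)[3])        # mode-1 unfolding
  G1 <- Ai %*% X1                                   # F x (I J)
  G <- array(G1, dim = c(F_, dim(X)[2], dim(X)[3]))
  # apply Bi along mode 2 and Ci along mode 3
  G2 <- array(0, dim = c(F_, F_, dim(X)[3]))
  for (k in seq_len(dim(X)[3])) G2[, , k] <- G[, , k] %*% t(Bi)
  core <- array(0, dim = c(F_, F_, F_))
  for (f in seq_len(F_)) core[f, , ] <- G2[f, , ] %*% t(Ci)
  target <- array(0, dim = c(F_, F_, F_))
  for (f in seq_len(F_)) target[f, f, f] <- 1
  100 * (1 - sum((core - target)^2) / F_)
}

#' Split-half validation of a PARAFAC model
#'
#' Randomly splits the samples into two halves, fits each half independently
#' at the same rank, matches components across halves by loading congruence,
#' and reports the minimum excitation/emission Tucker congruence over matched
#' components and modes. Values near 1 indicate the components are stable
#' features of the data rather than artifacts of a particular sample set.
#'
#' @inheritParams fit_parafac
#' @param ... further arguments passed to [fit_parafac()].
#' @return A list with `min_congruence` and the two fitted halves.
#' @export
split_half_validate <- function(cube, n_components = 6L, seed = 1L, ...) {
  n <- dim(cube$tensor)[1]
  if (n < 2 * n_components) {
    abort("domain error: split-half needs at least 2 * n_components samples")
  }
  set.seed(derive_seed(seed, "split_half"))
  idx <- sample(n)
  halves <- list(sort(idx[seq_len(floor(n / 2))]),
                 sort(idx[(floor(n / 2) + 1):n]))
  fits <- purrr::map(seq_along(halves), function(h) {
    sub <- halves[[h]]
    sub_cube <- structure(list(
      sample_ids = cube$sample_ids[sub], ex_nm = cube$ex_nm,
      em_nm = cube$em_nm, tensor = cube$tensor[sub, , , drop = FALSE],
      mask = cube$mask), class = "eem_cube")
    fit_parafac(sub_cube, n_components = n_components,
                seed = derive_seed(seed, paste0("half_", h)), ...)
  })
  # match components of half 2 to half 1 by summed ex+em congruence
  perm <- best_assignment(fits[[1]], fits[[2]])
  congs <- vapply(seq_len(n_components), function(f) {
    g <- perm[f]
    min(congruence(fits[[1]]$ex_loadings[, f], fits[[2]]$ex_loadings[, g]),
        congruence(fits[[1]]$em_loadings[, f], fits[[2]]$em_loadings[, g]))
  }, numeric(1))
  list(min_congruence = min(congs), congruences = congs, fits = fits)
}

# exact one-to-one assignment maximizing summed ex+em congruence
best_assignment <- function(ref, other) {
  F_ <- ref$n_components
  S <- matrix(0, F_, F_)
  for (f in seq_len(F_)) {
    for (g in seq_len(F_)) {
      cx <- congruence(ref$ex_loadings[, f], other$ex_loadings[, g])
      cm <- congruence(ref$em_loadings[, f], other$em_loadings[, g])
      S[f, g] <- sum(c(cx, cm), na.rm = TRUE)
    }
  }
  perms <- all_permutations(F_)
  scores <- vapply(perms, function(p) sum(S[cbind(seq_len(F_), p)]),
                   numeric(1))
  perms[[which.max(scores)]]  # ties: first (component-order) permutation wins
}

all_permutations <- function(k) {
  if (k == 1) return(list(1L))
  sub <- all_permutations(k - 1L)
  out <- list()
  for (p in sub) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
    }
  }
  out
}

#' Per-sample fractional component contributions
#'
#' Expresses each sample's PARAFAC scores as fractions of its total
#' fluorescence: `fraction_f = score_f / sum(scores)`. Rows sum to one where
#' defined; a sample with all-zero scores is flagged undefined.
#'
#' @param model a [fit_parafac()] model.
#' @return A tibble with `sample_id`, one `frac_*` column per component
#'   (named by matched labels when available, else F1..Fk), and `defined`.
#' @export
component_fractions <- function(model) {
  labels <- model$labels %||% paste0("F", seq_len(model$n_components))
  tot <- rowSums(model$scores)
  frac <- model$scores / ifelse(tot > 0, tot, NA_real_)
  colnames(frac) <- paste0("frac_", labels)
  out <- tibble::tibble(sample_id = model$sample_ids,
                        as.data.frame(frac),
                        defined = tot > 0)
  if (any(!out$defined)) warn("samples with all-zero scores flagged undefined")
  out
}

#' Match fitted components to a reference library
#'
#' Assigns each fitted component the library label that maximizes the summed
#' excitation + emission Tucker congruence under an exact one-to-one
#' assignment (all permutations are scored; ties break by component order).
#' Matches with congruence below 0.8 in either mode are flagged.
#'
#' @param model a [fit_parafac()] model whose grids equal the library's.
#' @param library a [gen_component_library()] (or any object with
#'   `ex_profiles`, `em_profiles`, `labels`, `names`).
#' @return The model with `labels`, `match_congruence` (per component,
#'   minimum over modes) and `match_flagged` filled in.
#' @export
match_components <- function(model, library) {
  if (!isTRUE(all.equal(model$ex_nm, library$ex_grid)) ||
      !isTRUE(all.equal(model$em_nm, library$em_grid))) {
    abort("model and library grids differ")
  }
  ref <- list(n_components = model$n_components,
              ex_loadings = library$ex_profiles,
              em_loadings = library$em_profiles)
  # perm[f] = fitted component assigned to library slot f
  perm <- best_assignment(ref, model)
  inv <- order(perm)
  labels <- library$labels[inv]
  cong <- vapply(seq_len(model$n_components), function(g) {
    f <- inv[g]  # library slot matched to fitted component g
    min(congruence(library$ex_profiles[, f], model$ex_loadings[, g]),
        congruence(library$em_profiles[, f], model$em_loadings[, g]),
        na.rm = FALSE)
  }, numeric(1))
  model$labels <- labels
  model$match_congruence <- cong
  model$match_flagged <- !is.na(cong) & cong < 0.8 | is.na(cong)
  model
}
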