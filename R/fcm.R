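#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means with fuzzifier `m`: alternating updates of cluster
#' centres (membership-weighted means) and memberships
#' `u_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1))` until the membership matrix
#' changes by less than `tol` in the max norm. Points coincident with a centre
#' receive membership 1 split equally across the coincident centres. The
#' objective `sum_ik u_ik^m d_ik^2` is non-increasing across iterations.
#'
#' @param points A numeric matrix or data frame (rows = observations).
#' @param c Number of clusters (2 <= c <= n).
#' @param m Fuzzifier (> 1; default 2).
#' @param tol Convergence tolerance on the membership matrix.
#' @param max_iter Iteration cap.
#' @param seed Seed for the random membership initialisation.
#' @param standardize Centre/scale each axis to zero mean and unit variance
#'   before clustering (centres are reported on the original scale).
#' @return An `fcm_fit`: `centers`, `membership` (n x c, rows sum to 1),
#'   `pc`, `mpc`, `objective`, `iterations`, `cluster` (hard assignment,
#'   ties to the lowest index), `standardization`.
#' @export
fuzzy_cmeans <- function(points, c, m = 2, tol = 1e-8, max_iter = 1000,
                         seed = 1, standardize = TRUE) {
  X <- as.matrix(points)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (!all(is.finite(X))) stopf("points must be finite")
  if (c < 2 || c > n) stopf("need 2 <= c <= n (n = %d, c = %d)", n, c)
  if (m <= 1) stopf("fuzzifier m must be > 1")

  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (standardize) {
    ctr <- colMeans(X)
    scl <- apply(X, 2, sd)
    scl[scl < 1e-12] <- 1
    X <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  }

  U <- with_seed(derive_seed(seed, "fcm-init", c), {
    u0 <- matrix(runif(n * c), n, c)
    u0 / rowSums(u0)
  })

  obj <- Inf
  obj_trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    Um <- U^m
    V <- t(Um) %*% X / colSums(Um)           # c x p centres
    D2 <- outer(rowSums(X^2), rep(1, c)) -
      2 * X %*% t(V) + outer(rep(1, n), rowSums(V^2))
    D2 <- pmax(D2, 0)
    zero <- D2 < 1e-300
    Unew <- matrix(0, n, c)
    any_zero <- rowSums(zero) > 0
    if (any(any_zero)) {
      Unew[any_zero, ] <- zero[any_zero, , drop = FALSE] /
        rowSums(zero[any_zero, , drop = FALSE])
    }
    ok <- !any_zero
    if (any(ok)) {
      P <- D2[ok, , drop = FALSE]^(-1 / (m - 1))
      Unew[ok, ] <- P / rowSums(P)
    }
    obj_new <- sum(Unew^m * D2)
    obj_trace <- c(obj_trace, obj_new)
    delta <- max(abs(Unew - U))
    U <- Unew
    obj <- obj_new
    if (delta < tol || iter >= max_iter) break
  }

  hard <- max.col(U, ties.method = "first")
  centers <- sweep(sweep(V, 2, scl, "*"), 2, ctr, "+")
  colnames(centers) <- colnames(points) %||% paste0("x", seq_len(ncol(X)))
  pc <- mean(rowSums(U^2))
  structure(
    list(c = c, m = m, centers = centers, membership = U,
         pc = pc, mpc = mpc(U), objective = obj, objective_trace = obj_trace,
         iterations = iter,
         cluster = hard, seed = seed,
         standardization = list(center = ctr, scale = scl),
         converged = iter < max_iter),
    class = "fcm_fit"
  )
}

#' Partition coefficient and modified partition coefficient
#'
#' `PC = (1/n) sum_ik u_ik^2` measures partition crispness (1/c for a uniform
#' partition, 1 for a crisp one). The modified partition coefficient rescales
#' it to \[0, 1\]: `MPC = 1 - c/(c-1) * (1 - PC)`, so 0 means no cluster
#' structure and 1 a perfectly crisp partition.
#'
#' @param U Membership matrix (n x c, rows summing to 1) or an `fcm_fit`.
#' @return MPC value in \[0, 1\].
#' @export
mpc <- function(U) {
  if (inherits(U, "fcm_fit")) U <- U$membership
  U <- as.matrix(U)
  cc <- ncol(U)
  pc <- mean(rowSums(U^2))
  1 - cc / (cc - 1) * (1 - pc)
}

#' Select the cluster count by maximising the MPC
#'
#' Runs fuzzy c-means for each candidate cluster count with multiple seeded
#' restarts (best objective per count), then returns the model whose count
#' maximises the modified partition coefficient. A winning MPC below
#' `structure_floor` is flagged as "no cluster structure".
#'
#' @param points Observations (matrix or data frame).
#' @param c_range Candidate cluster counts (default 2:8).
#' @param m Fuzzifier.
#' @param n_restarts Seeded restarts per count.
#' @param seed Base seed.
#' @param structure_floor MPC below which the result is flagged structureless.
#' @param ... Passed to [fuzzy_cmeans()].
#' @return The best `fcm_fit`, with extra fields `mpc_table` (tibble c, mpc,
#'   objective) and `structure` (logical flag).
#' @export
select_cluster_count <- function(points, c_range = 2:8, m = 2,
                                 n_restarts = 10, seed = 1,
                                 structure_floor = 0.5, ...) {
  if (!length(c_range)) stopf("`c_range` must be non-empty")
  n <- nrow(as.matrix(points))
  c_range <- c_range[c_range >= 2 & c_range <= n - 1]
  if (!length(c_range)) stopf("no feasible cluster count for n = %d", n)
  fits <- lapply(c_range, function(cc) {
    runs <- lapply(seq_len(n_restarts), function(r) {
      fuzzy_cmeans(points, cc, m = m, seed = derive_seed(seed, cc, r), ...)
    })
    runs[[which.min(vapply(runs, function(f) f$objective, numeric(1)))]]
  })
  mpcs <- vapply(fits, function(f) f$mpc, numeric(1))
  best <- fits[[which.max(mpcs)]]
  best$mpc_table <- tibble::tibble(
    c = c_range, mpc = mpcs,
    objective = vapply(fits, function(f) f$objective, numeric(1))
  )
  best$structure <- best$mpc >= structure_floor
  best
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf("<fcm_fit> c=%d m=%g MPC=%.4f PC=%.4f (%d iterations)\n",
              x$c, x$m, x$mpc, x$pc, x$iterations))
  if (!is.null(x$structure) && !x$structure) {
    cat("  flag: no cluster structure (low MPC)\n")
  }
  invisible(x)
}

#' Project new points onto a fitted fuzzy partition
#'
#' Computes memberships of new observations with the model's centres frozen
#' (same standardization), so cluster identity is preserved across conditions.
#'
#' @param model An `fcm_fit`.
#' @param points New observations on the original scale.
#' @return Membership matrix (rows sum to 1) with attribute `cluster` (hard
#'   assignment).
#' @export
fcm_project <- function(model, points) {
  X <- as.matrix(points)
  X <- sweep(sweep(X, 2, model$standardization$center), 2,
             model$standardization$scale, "/")
  V <- sweep(sweep(model$centers, 2, model$standardization$center), 2,
             model$standardization$scale, "/")
  n <- nrow(X); cc <- nrow(V)
  D2 <- outer(rowSums(X^2), rep(1, cc)) - 2 * X %*% t(V) +
    outer(rep(1, n), rowSums(V^2))
  D2 <- pmax(D2, 0)
  U <- matrix(0, n, cc)
  zero <- D2 < 1e-300
  any_zero <- rowSums(zero) > 0
  if (any(any_zero)) {
    U[any_zero, ] <- zero[any_zero, , drop = FALSE] /
      rowSums(zero[any_zero, , drop = FALSE])
  }
  ok <- !any_zero
  if (any(ok)) {
    P <- D2[ok, , drop = FALSE]^(-1 / (model$m - 1))
    U[ok, ] <- P / rowSums(P)
  }
  attr(U, "cluster") <- max.col(U, ties.method = "first")
  U
}
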