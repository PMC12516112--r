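# Discretized design space, optimality criteria, and the exchange optimizer
# allocating calibration items to ability intervals.

#' Build a design grid on the ability axis
#'
#' Divides `[lo, hi]` into equal cells of width `step`.  Cell midpoints carry
#' the population ability density (standard normal by default), so that a
#' design is a row-stochastic weight matrix over cells x items.
#'
#' @param lo,hi Domain endpoints (defaults -6, 6).
#' @param step Cell width (default .01); must divide `hi - lo`.
#' @param density Population density of ability estimates (default
#'   [stats::dnorm()]).
#' @return An object of class `"design_grid"` with fields `boundaries`,
#'   `midpoints`, `step`, `J` and cached density values `htot`.
#' @export
build_grid <- function(lo = -6, hi = 6, step = 0.01, density = stats::dnorm) {
  if (!is.numeric(step) || step <= 0) stop("'step' must be positive",
                                           call. = FALSE)
  if (lo >= hi) stop("'lo' must be below 'hi'", call. = FALSE)
  J <- round((hi - lo) / step)
  if (abs(J * step - (hi - lo)) > 1e-8)
    stop("'step' must divide the interval length", call. = FALSE)
  boundaries <- lo + step * (0:J)
  midpoints <- (boundaries[-1L] + boundaries[-(J + 1L)]) / 2
  structure(list(boundaries = boundaries, midpoints = midpoints,
                 step = step, J = as.integer(J), htot = density(midpoints),
                 density = density),
            class = "design_grid")
}

#' @export
print.design_grid <- function(x, ...) {
  cat(sprintf("<design grid> [%g, %g], step %g, %d cells\n",
              x$boundaries[1L], x$boundaries[length(x$boundaries)],
              x$step, x$J))
  invisible(x)
}

.new_design <- function(grid, weights) {
  stopifnot(nrow(weights) == grid$J)
  rs <- rowSums(weights)
  if (any(weights < -1e-12) || any(abs(rs - 1) > 1e-8))
    stop("design weights must be nonnegative with unit row sums",
         call. = FALSE)
  structure(list(grid = grid, weights = weights), class = "calib_design")
}

#' Random reference design
#'
#' Allocates every cell to each of the n calibration items with equal weight
#' 1/n: the benchmark design that ignores ability information.
#'
#' @param n Number of calibration items.
#' @param grid A [build_grid()].
#' @return A `"calib_design"`.
#' @export
random_design <- function(n, grid = build_grid()) {
  stopifnot(n >= 1)
  .new_design(grid, matrix(1 / n, grid$J, n))
}

#' @export
print.calib_design <- function(x, ...) {
  n <- ncol(x$weights)
  frac <- any(x$weights > 1e-9 & x$weights < 1 - 1e-9)
  cat(sprintf("<calibration design> %d item(s) on %d cells (%s)\n", n,
              x$grid$J, if (frac) "fractional" else "0/1"))
  if (!frac) print(extract_intervals(x))
  invisible(x)
}

#' D-optimality criterion
#'
#' Maximizes the determinant of the block information matrix (equivalently
#' the product of block determinants).
#' @return A `"design_criterion"` of kind `"D"`.
#' @export
criterion_d <- function() structure(list(kind = "D"),
                                    class = "design_criterion")

#' L-optimality criterion
#'
#' Minimizes \eqn{\sum_i \mathrm{tr}(M_i^{-1} L_i)} for symmetric PSD
#' matrices \eqn{L_i}.
#'
#' @param L A single p x p matrix (recycled over items) or a list of per-item
#'   matrices.
#' @return A `"design_criterion"` of kind `"L"`.
#' @export
criterion_l <- function(L) {
  if (is.matrix(L)) L <- list(L)
  stopifnot(all(vapply(L, is.matrix, logical(1))))
  structure(list(kind = "L", L = L), class = "design_criterion")
}

#' c-optimality criterion
#'
#' The L-criterion with \eqn{L = c c^T}, targeting the variance of a single
#' linear combination of an item's parameters; `c = (1, 0)` targets the
#' discrimination and `c = (0, 1)` the difficulty of a 2PL item.
#'
#' @param c_vec A numeric vector (recycled over items) or list of vectors.
#' @return A `"design_criterion"` of kind `"L"`.
#' @export
criterion_c <- function(c_vec) {
  if (!is.list(c_vec)) c_vec <- list(c_vec)
  criterion_l(lapply(c_vec, tcrossprod))
}

# per-item L matrices aligned with the bank
.l_matrices <- function(criterion, items) {
  stopifnot(criterion$kind == "L")
  L <- criterion$L
  if (length(L) == 1L) L <- rep(L, length(items))
  if (length(L) != length(items))
    stop("criterion must supply one L matrix per item", call. = FALSE)
  L
}

.logdet <- function(m) {
  d <- determinant(m, logarithm = TRUE)
  if (d$sign <= 0) -Inf else as.numeric(d$modulus)
}

# criterion value on a list of blocks, oriented so larger is better
.crit_value <- function(blocks, criterion, items) {
  if (criterion$kind == "D") {
    sum(vapply(blocks, .logdet, numeric(1)))
  } else {
    L <- .l_matrices(criterion, items)
    -sum(vapply(seq_along(blocks), function(i)
      sum(diag(solve(blocks[[i]], L[[i]]))), numeric(1)))
  }
}

#' Sensitivity (directional derivative) of a design criterion
#'
#' For D-optimality the directional derivative of log det towards allocating
#' ability `t` to item `item_index`: \eqn{\mathrm{tr}(M_i^{-1}\mu_i(t))},
#' where \eqn{\mu_i(t)} is the item's elemental information at `t` under the
#' uncertainty model.  At a D-optimal design, every cell's assigned item
#' attains the maximum of this quantity over items (an equivalence-theorem
#' style check).  For the L-criterion the analogous normalized derivative
#' \eqn{\mathrm{tr}(M_i^{-1} L_i M_i^{-1} \mu_i(t)) /
#' \mathrm{tr}(M_i^{-1} L_i)} is returned.
#'
#' @param design A `"calib_design"` (supplies the grid).
#' @param item_index 1-based item index.
#' @param t Ability value.
#' @param M [block_info()] assembled for the design.
#' @param criterion A `"design_criterion"`.
#' @param uncertainty The [uncertainty_model()] the design was computed under.
#' @param items The calibration [item_bank()].
#' @param nodes Gauss-Hermite node count.
#' @return A single numeric sensitivity value.
#' @export
sensitivity <- function(design, item_index, t, M, criterion = criterion_d(),
                        uncertainty = uncertainty_model("known"), items,
                        nodes = .GH_NODES) {
  item <- items[[item_index]]
  mu <- if (uncertainty$kind == "known") elemental_info_known(item, t)
        else elemental_info_uncertain(item, .prior_at(uncertainty, t), nodes)
  Mi <- M$blocks[[item_index]]
  if (criterion$kind == "D") {
    sum(diag(solve(Mi, mu)))
  } else {
    L <- .l_matrices(criterion, items)[[item_index]]
    A <- solve(Mi, L)
    sum(diag(solve(Mi, t(A)) %*% mu)) / sum(diag(A))
  }
}

# Exchange worker, fast path: all items 2PL, D-criterion.  Block matrices are
# held as scalars (m11, m12, m22); each cell move uses the exact change in
# log-determinant.  Cells whose move gain is numerically indifferent (deep
# tails) are settled by the sensitivity direction tr(M_i^{-1} E_ij) so the
# final assignment extends the interval structure across the whole axis.
.exchange_2pl_d <- function(elems, mass, assign, tol, max_iter) {
  J <- length(mass)
  n <- length(elems)
  e11 <- lapply(elems, function(e) e[1L, ])
  e12 <- lapply(elems, function(e) e[2L, ])
  e22 <- lapply(elems, function(e) e[4L, ])
  m11 <- m12 <- m22 <- numeric(n)
  for (i in seq_len(n)) {
    sel <- mass * (assign == i)
    m11[i] <- sum(e11[[i]] * sel)
    m12[i] <- sum(e12[[i]] * sel)
    m22[i] <- sum(e22[[i]] * sel)
  }
  # determinants below this relative level are cancellation noise from a
  # rank-deficient block, not information
  ok2 <- function(d, x11, x22) d > 1e-10 * x11 * x22
  dets <- m11 * m22 - m12^2
  if (any(!ok2(dets, m11, m22)))
    stop("an item has a singular information block at initialization; ",
         "use a finer grid or a different init", call. = FALSE)
  total <- sum(log(dets))
  path <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    moved <- 0L
    thr_gain <- tol * (1 + abs(total))
    thr_zero <- 1e-11 * (1 + abs(total))
    for (j in seq_len(J)) {
      cur <- assign[j]
      mj <- mass[j]
      c11 <- e11[[cur]][j] * mj; c12 <- e12[[cur]][j] * mj
      c22 <- e22[[cur]][j] * mj
      d_less <- (m11[cur] - c11) * (m22[cur] - c22) - (m12[cur] - c12)^2
      if (!ok2(d_less, m11[cur] - c11, m22[cur] - c22))
        next   # item cannot give up this cell
      gains <- rep(-Inf, n)
      for (k in seq_len(n)) {
        if (k == cur) next
        a11 <- e11[[k]][j] * mj; a12 <- e12[[k]][j] * mj
        a22 <- e22[[k]][j] * mj
        d_new <- (m11[k] + a11) * (m22[k] + a22) - (m12[k] + a12)^2
        if (!ok2(d_new, m11[k] + a11, m22[k] + a22)) next
        gains[k] <- log(d_new) - log(dets[k]) + log(d_less) - log(dets[cur])
      }
      best_k <- which.max(gains)
      do_move <- FALSE
      if (gains[best_k] > thr_gain) {
        do_move <- TRUE
      } else {
        # numerically indifferent: settle by the directional derivative,
        # requiring a clear relative margin so exact ties stay put
        s <- (m22 * vapply(e11, `[`, 0, j) -
                2 * m12 * vapply(e12, `[`, 0, j) +
                m11 * vapply(e22, `[`, 0, j)) / dets
        ks <- which.max(s)
        if (ks != cur && s[ks] - s[cur] > 1e-9 * (abs(s[ks]) + abs(s[cur])) &&
            is.finite(gains[ks]) && gains[ks] > -thr_zero) {
          best_k <- ks; do_move <- TRUE
        }
      }
      if (do_move) {
        k <- best_k
        a11 <- e11[[k]][j] * mj; a12 <- e12[[k]][j] * mj
        a22 <- e22[[k]][j] * mj
        m11[cur] <- m11[cur] - c11; m12[cur] <- m12[cur] - c12
        m22[cur] <- m22[cur] - c22
        m11[k] <- m11[k] + a11; m12[k] <- m12[k] + a12
        m22[k] <- m22[k] + a22
        dets[cur] <- m11[cur] * m22[cur] - m12[cur]^2
        dets[k] <- m11[k] * m22[k] - m12[k]^2
        assign[j] <- k
        moved <- moved + 1L
      }
    }
    total <- sum(log(dets))
    path <- c(path, total)
    if (moved == 0L) {
      # on coarse grids single-cell moves can be blocked by singularity
      # barriers; try exact two-cell swaps before declaring convergence
      if (J <= 400L) {
        swap <- .best_swap_2pl(assign, e11, e12, e22, m11, m12, m22, dets,
                               mass, tol * (1 + abs(total)))
        if (!is.null(swap)) {
          j <- swap$j; j2 <- swap$j2
          i <- assign[j]; k <- assign[j2]
          for (co in list(list(i, j, -1), list(i, j2, +1),
                          list(k, j, +1), list(k, j2, -1))) {
            ii <- co[[1]]; jj <- co[[2]]; sgn <- co[[3]]
            m11[ii] <- m11[ii] + sgn * e11[[ii]][jj] * mass[jj]
            m12[ii] <- m12[ii] + sgn * e12[[ii]][jj] * mass[jj]
            m22[ii] <- m22[ii] + sgn * e22[[ii]][jj] * mass[jj]
          }
          dets[i] <- m11[i] * m22[i] - m12[i]^2
          dets[k] <- m11[k] * m22[k] - m12[k]^2
          assign[j] <- k; assign[j2] <- i
          total <- sum(log(dets))
          path[length(path)] <- total
          next
        }
      }
      converged <- TRUE
      break
    }
  }
  list(assign = assign, total = total, path = path, converged = converged)
}

# best improving simultaneous exchange of two cells between their items
.best_swap_2pl <- function(assign, e11, e12, e22, m11, m12, m22, dets, mass,
                           thr) {
  J <- length(assign)
  best <- thr
  out <- NULL
  for (j in seq_len(J - 1L)) {
    i <- assign[j]
    for (j2 in (j + 1L):J) {
      k <- assign[j2]
      if (k == i) next
      ni11 <- m11[i] - e11[[i]][j] * mass[j] + e11[[i]][j2] * mass[j2]
      ni12 <- m12[i] - e12[[i]][j] * mass[j] + e12[[i]][j2] * mass[j2]
      ni22 <- m22[i] - e22[[i]][j] * mass[j] + e22[[i]][j2] * mass[j2]
      di <- ni11 * ni22 - ni12^2
      if (di <= 1e-10 * ni11 * ni22) next
      nk11 <- m11[k] + e11[[k]][j] * mass[j] - e11[[k]][j2] * mass[j2]
      nk12 <- m12[k] + e12[[k]][j] * mass[j] - e12[[k]][j2] * mass[j2]
      nk22 <- m22[k] + e22[[k]][j] * mass[j] - e22[[k]][j2] * mass[j2]
      dk <- nk11 * nk22 - nk12^2
      if (dk <= 1e-10 * nk11 * nk22) next
      gain <- log(di) - log(dets[i]) + log(dk) - log(dets[k])
      if (gain > best) { best <- gain; out <- list(j = j, j2 = j2) }
    }
  }
  out
}

# Exchange worker, generic path (3PL blocks and/or L-criterion).
.exchange_generic <- function(items, elems, mass, assign, criterion, tol,
                              max_iter) {
  J <- length(mass)
  n <- length(items)
  pdim <- vapply(items, .npar, integer(1))
  Ld <- if (criterion$kind == "L") .l_matrices(criterion, items) else NULL
  cell_mat <- function(i, j, scale = mass[j])
    matrix(elems[[i]][, j] * scale, pdim[i], pdim[i])
  blocks <- lapply(seq_len(n), function(i)
    matrix(drop(elems[[i]] %*% (mass * (assign == i))), pdim[i], pdim[i]))
  bval <- function(i, m) {
    if (det(m) <= 1e-10 * prod(diag(m))) return(-Inf)
    if (criterion$kind == "D") .logdet(m)
    else {
      d <- tryCatch(sum(diag(solve(m, Ld[[i]]))), error = function(e) Inf)
      if (!is.finite(d) || d < 0) -Inf else -d
    }
  }
  sens <- function(i, j) {
    E <- cell_mat(i, j, 1)
    if (criterion$kind == "D") {
      sum(diag(solve(blocks[[i]], E)))
    } else {
      A <- solve(blocks[[i]], Ld[[i]])
      sum(diag(solve(blocks[[i]], t(A)) %*% E)) / sum(diag(A))
    }
  }
  vals <- vapply(seq_len(n), function(i) bval(i, blocks[[i]]), numeric(1))
  if (any(!is.finite(vals)))
    stop("an item has a singular information block at initialization; ",
         "use a finer grid or a different init", call. = FALSE)
  total <- sum(vals)
  path <- numeric(0)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    moved <- 0L
    thr_gain <- tol * (1 + abs(total))
    thr_zero <- 1e-11 * (1 + abs(total))
    for (j in seq_len(J)) {
      cur <- assign[j]
      Ccur <- cell_mat(cur, j)
      val_cur_less <- bval(cur, blocks[[cur]] - Ccur)
      if (!is.finite(val_cur_less)) next
      gains <- rep(-Inf, n)
      for (k in seq_len(n)) {
        if (k == cur) next
        gains[k] <- bval(k, blocks[[k]] + cell_mat(k, j)) - vals[k] +
          val_cur_less - vals[cur]
      }
      best_k <- which.max(gains)
      do_move <- is.finite(gains[best_k]) && gains[best_k] > thr_gain
      if (!do_move) {
        s <- vapply(seq_len(n), sens, numeric(1), j = j)
        ks <- which.max(s)
        if (ks != cur && s[ks] - s[cur] > 1e-9 * (abs(s[ks]) + abs(s[cur])) &&
            is.finite(gains[ks]) && gains[ks] > -thr_zero) {
          best_k <- ks; do_move <- TRUE
        }
      }
      if (do_move) {
        k <- best_k
        blocks[[cur]] <- blocks[[cur]] - Ccur
        blocks[[k]] <- blocks[[k]] + cell_mat(k, j)
        vals[cur] <- bval(cur, blocks[[cur]])
        vals[k] <- bval(k, blocks[[k]])
        assign[j] <- k
        moved <- moved + 1L
      }
    }
    total <- sum(vals)
    path <- c(path, total)
    if (moved == 0L) { converged <- TRUE; break }
  }
  list(assign = assign, total = total, path = path, converged = converged)
}

#' Optimal allocation of calibration items to ability intervals
#'
#' Exchange algorithm on the discretized ability axis: starting from a
#' round-robin assignment, sweep the cells and move each cell to the item
#' whose criterion gain (exact change in log-determinant for D, in trace for
#' L) is largest, until a full sweep makes no move.  The criterion value is
#' non-decreasing across moves by construction.  Since no two items share a
#' parameter vector in the intended use, the optimum allocates each cell
#' wholly to one item, yielding an interval partition of the ability axis.
#'
#' @param items Calibration [item_bank()].
#' @param grid A [build_grid()].
#' @param uncertainty An [uncertainty_model()] (`"known"` or `"normal"`).
#' @param criterion A `"design_criterion"` (default D-optimality).
#' @param tol Relative criterion-change threshold treated as no improvement.
#' @param max_iter Maximum number of sweeps.
#' @param init `"roundrobin"` (deterministic default) or `"random"`.
#' @param seed Seed for the random initialization.
#' @param restarts Number of additional deterministic starting assignments
#'   (round-robin phase shifts, then pseudo-random fills).  Coarse grids
#'   raise singularity barriers that can trap single-cell exchanges in local
#'   optima, so the default is 8 restarts when the grid has at most 2000
#'   cells per item and 0 on fine grids, where the round-robin start is
#'   reliable.  The best converged design is returned.
#' @param nodes Gauss-Hermite node count for the inner integral.
#' @return A `"calib_design"` with 0/1 weights and attributes
#'   `criterion_value` (log-det for D, negative trace for L),
#'   `criterion_path` (value after each sweep), `iterations` and `converged`.
#' @export
optimize_design <- function(items, grid = build_grid(),
                            uncertainty = uncertainty_model("known"),
                            criterion = criterion_d(), tol = 1e-8,
                            max_iter = 500L,
                            init = c("roundrobin", "random"), seed = NULL,
                            restarts = NULL, nodes = .GH_NODES) {
  init <- match.arg(init)
  n <- length(items)
  J <- grid$J
  elems <- .elemental_grid(items, grid, uncertainty, nodes)
  mass <- grid$htot * grid$step
  if (is.null(restarts)) restarts <- if (J * n <= 2000L) 8L else 0L
  first <- if (init == "roundrobin") {
    ((seq_len(J) - 1L) %% n) + 1L
  } else {
    if (!is.null(seed)) set.seed(seed)
    sample.int(n, J, replace = TRUE)
  }
  inits <- c(list(first), lapply(seq_len(restarts), function(r) {
    if (r < n) ((seq_len(J) - 1L + r) %% n) + 1L   # phase-shifted round robin
    else {  # deterministic LCG fill, independent of the global RNG state
      x <- as.double(r * 7654321) %% 2^31
      vapply(seq_len(J), function(j) {
        x <<- (69069 * x + 1234567) %% 2^31   # exact in double precision
        as.integer(x %% n) + 1L
      }, integer(1))
    }
  }))
  run_one <- function(a0) {
    tryCatch({
      if (criterion$kind == "D" &&
          all(vapply(items, .npar, integer(1)) == 2L))
        .exchange_2pl_d(elems, mass, a0, tol, max_iter)
      else
        .exchange_generic(items, elems, mass, a0, criterion, tol, max_iter)
    }, error = function(e) NULL)
  }
  res <- NULL
  for (a0 in inits) {
    cand <- run_one(a0)
    if (!is.null(cand) && (is.null(res) || cand$total > res$total))
      res <- cand
  }
  if (is.null(res))
    stop("no feasible starting assignment: an item has a singular ",
         "information block under every initialization; use a finer grid",
         call. = FALSE)
  if (!res$converged)
    warning("exchange algorithm did not converge in ", max_iter, " sweeps",
            call. = FALSE)
  W <- matrix(0, J, n)
  W[cbind(seq_len(J), res$assign)] <- 1
  out <- .new_design(grid, W)
  total <- res$total
  path <- res$path
  converged <- res$converged
  attr(out, "criterion") <- criterion$kind
  attr(out, "criterion_value") <- total
  attr(out, "criterion_path") <- path
  attr(out, "iterations") <- length(path)
  attr(out, "converged") <- converged
  out
}

#' Ability intervals of a 0/1 design
#'
#' Collapses consecutive cells assigned to the same item into maximal
#' intervals; the intervals partition the grid domain and adjacent intervals
#' carry different items.
#'
#' @param design A 0/1 `"calib_design"`.
#' @return A data frame with columns `lower`, `upper`, `item`.
#' @export
extract_intervals <- function(design) {
  W <- design$weights
  if (any(W > 1e-9 & W < 1 - 1e-9))
    stop("intervals are only defined for 0/1 designs", call. = FALSE)
  assign <- max.col(W)
  r <- rle(assign)
  upper_idx <- cumsum(r$lengths)
  lower_idx <- c(1L, utils::head(upper_idx, -1L) + 1L)
  data.frame(lower = design$grid$boundaries[lower_idx],
             upper = design$grid$boundaries[upper_idx + 1L],
             item = r$values)
}

#' Rebuild a 0/1 design from an interval table
#'
#' Inverse of [extract_intervals()]: cells whose midpoint falls in
#' `[lower, upper)` (last interval closed) get the interval's item.
#'
#' @param intervals Data frame with columns `lower`, `upper`, `item`.
#' @param grid A [build_grid()].
#' @return A `"calib_design"`.
#' @export
intervals_to_design <- function(intervals, grid = build_grid()) {
  n <- max(intervals$item)
  W <- matrix(0, grid$J, n)
  for (k in seq_len(nrow(intervals))) {
    sel <- grid$midpoints >= intervals$lower[k] &
      grid$midpoints < intervals$upper[k]
    W[sel, intervals$item[k]] <- 1
  }
  W[grid$midpoints >= intervals$upper[nrow(intervals)],
    intervals$item[nrow(intervals)]] <- 1
  .new_design(grid, W)
}

#' Write a design's interval table to CSV
#'
#' Columns `lower,upper,item`, endpoints rounded to 4 decimals.
#'
#' @param design A 0/1 `"calib_design"`.
#' @param path Output path.
#' @export
write_intervals <- function(design, path) {
  iv <- extract_intervals(design)
  iv$lower <- round(iv$lower, 4)
  iv$upper <- round(iv$upper, 4)
  utils::write.csv(iv, path, row.names = FALSE)
  invisible(path)
}
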