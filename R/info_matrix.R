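# Elemental and standardized (block-diagonal) information matrices, under
# known abilities, the normal uncertainty approximation, or posterior draws.

# cached Gauss-Hermite rules (probabilists' use via change of variables)
.gh_env <- new.env(parent = emptyenv())
.gauss_hermite <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_env[[key]])) .gh_env[[key]] <- pracma::gaussHermite(n)
  .gh_env[[key]]
}

# default inner-integral rule: 61 nodes gives < 1e-10 error for the smooth
# logistic x Gaussian integrands at the variances arising here
.GH_NODES <- 61L

#' Expected response probability under ability uncertainty
#'
#' \eqn{\tilde p(\hat\theta) = \int p(\theta) g(\theta|\hat\theta) d\theta}:
#' the response probability averaged over the uncertainty prior.  Point
#' priors return `prob()` exactly; normal priors use Gauss-Hermite
#' quadrature; draw priors average over the draws.
#'
#' @param item An [irt_item()].
#' @param prior An [ability_prior()].
#' @param nodes Gauss-Hermite node count for normal priors.
#' @return A probability in (0, 1).
#' @export
ptilde <- function(item, prior, nodes = .GH_NODES) {
  switch(prior$kind,
    point  = prob(item, prior$mean),
    normal = {
      gh <- .gauss_hermite(nodes)
      th <- prior$mean + sqrt(2 * prior$variance) * gh$x
      sum(gh$w * prob(item, th)) / sqrt(pi)
    },
    draws  = mean(prob(item, prior$draws)))
}

#' Psi vector of an item under ability uncertainty
#'
#' The componentwise integral \eqn{\Psi(\hat\theta) = \int
#' (\partial p/\partial\zeta)(\theta)\, g(\theta|\hat\theta) d\theta}, i.e.
#' the gradient of \eqn{\tilde p} in the item parameters.  For a 2PL item the
#' integrand is \eqn{p(1-p)\,(\theta-b,\,-a)}.
#'
#' @inheritParams ptilde
#' @return A numeric vector of length 2 (2PL) or 3 (3PL).
#' @export
psi_vector <- function(item, prior, nodes = .GH_NODES) {
  switch(prior$kind,
    point  = drop(.dprob_dzeta(item, prior$mean)),
    normal = {
      gh <- .gauss_hermite(nodes)
      th <- prior$mean + sqrt(2 * prior$variance) * gh$x
      drop(gh$w %*% .dprob_dzeta(item, th)) / sqrt(pi)
    },
    draws  = colMeans(.dprob_dzeta(item, prior$draws)))
}

#' Elemental information matrix under known ability
#'
#' \eqn{p(1-p)\,\nabla\eta\,\nabla\eta^T} evaluated at `theta`: the Fisher
#' information contribution of one examinee with known ability.
#'
#' @param item An [irt_item()].
#' @param theta A single ability value.
#' @return A symmetric positive semidefinite p x p matrix.
#' @export
elemental_info_known <- function(item, theta) {
  d <- drop(.dprob_dzeta(item, theta))
  p <- prob(item, theta)
  tcrossprod(d) / (p * (1 - p))
}

#' Elemental information matrix under ability uncertainty
#'
#' \eqn{\Psi\Psi^T / (\tilde p (1-\tilde p))}: the rank-1 uncertainty-adjusted
#' analogue of [elemental_info_known()].  At a point prior the two coincide.
#'
#' @inheritParams ptilde
#' @return A symmetric positive semidefinite rank-1 p x p matrix.
#' @export
elemental_info_uncertain <- function(item, prior, nodes = .GH_NODES) {
  pt <- ptilde(item, prior, nodes)
  if (pt <= .Machine$double.xmin || pt >= 1 - 1e-15)
    stop(sprintf(
      "expected probability numerically 0/1 for item (a=%g, b=%g) at %s",
      item$a, item$b,
      if (is.null(prior$mean)) "draw prior" else format(prior$mean)),
      call. = FALSE)
  psi <- psi_vector(item, prior, nodes)
  tcrossprod(psi) / (pt * (1 - pt))
}

#' Block-diagonal standardized information matrix
#'
#' @param blocks List of per-item symmetric information matrices.
#' @param items Optional 1-based item indices (default sequential).
#' @return An object of class `"block_info"`.
#' @export
block_info <- function(blocks, items = seq_along(blocks)) {
  stopifnot(length(blocks) >= 1L, length(items) == length(blocks))
  structure(list(blocks = blocks, items = as.integer(items)),
            class = "block_info")
}

#' @export
print.block_info <- function(x, ...) {
  cat(sprintf("<block information matrix> %d block(s)\n", length(x$blocks)))
  for (k in seq_along(x$blocks)) {
    cat(sprintf("item %d:\n", x$items[k]))
    print(round(x$blocks[[k]], 4))
  }
  invisible(x)
}

#' Per-block determinants
#'
#' @param M A [block_info()].
#' @return Numeric vector of block determinants; the determinant of the full
#'   block-diagonal matrix is their product.
#' @export
block_dets <- function(M) vapply(M$blocks, det, numeric(1))

#' Serialize a block information matrix to JSON
#'
#' @param M A [block_info()].
#' @param path Output path.
#' @export
write_block_info <- function(M, path) {
  jsonlite::write_json(
    list(items = M$items,
         blocks = lapply(M$blocks, function(b) unname(as.matrix(b)))),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a block information matrix from JSON
#'
#' @param path Path written by [write_block_info()].
#' @return A [block_info()].
#' @export
read_block_info <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  block_info(lapply(seq_len(dim(obj$blocks)[1]),
                    function(k) obj$blocks[k, , ]),
             items = obj$items)
}

# ---- grid engine -----------------------------------------------------------

# Per-item elemental matrices at every grid midpoint, under the uncertainty
# model.  Returns a list (one per item) of p^2 x J matrices whose columns are
# vec(E_ij); the vectorized form makes design assembly a matrix product.
.elemental_grid <- function(items, grid, uncertainty, nodes = .GH_NODES) {
  t <- grid$midpoints
  J <- length(t)
  if (uncertainty$kind == "known") {
    lapply(items, function(item) {
      D <- .dprob_dzeta(item, t)                     # J x p
      p <- prob(item, t)
      pq <- p * (1 - p)
      P <- ncol(D)
      out <- matrix(0, P * P, J)
      for (r in seq_len(P)) for (s in seq_len(P))
        out[(s - 1L) * P + r, ] <- D[, r] * D[, s] / pq
      out
    })
  } else if (uncertainty$kind == "normal") {
    info <- test_information(uncertainty$op_bank, t)
    if (any(!is.finite(info) | info <= 0))
      stop("operational test information non-positive on the grid",
           call. = FALSE)
    gh <- .gauss_hermite(nodes)
    K <- length(gh$x)
    sd2 <- sqrt(2 / info)
    TH <- outer(t, rep(1, K)) + outer(sd2, gh$x)     # J x K
    w <- gh$w / sqrt(pi)
    lapply(items, function(item) {
      p0 <- .logistic(item$a * (TH - item$b))
      p <- if (item$model == "3PL") item$c + (1 - item$c) * p0 else p0
      pt <- drop(p %*% w)
      P <- .npar(item)
      Psi <- matrix(0, J, P)
      if (item$model == "3PL") {
        f <- (p - item$c) * (1 - p) / (1 - item$c)
        Psi[, 1] <- ((TH - item$b) * f) %*% w
        Psi[, 2] <- (-item$a * f) %*% w
        Psi[, 3] <- ((1 - p) / (1 - item$c)) %*% w
      } else {
        pq <- p * (1 - p)
        Psi[, 1] <- ((TH - item$b) * pq) %*% w
        Psi[, 2] <- (-item$a * pq) %*% w
      }
      den <- pt * (1 - pt)
      out <- matrix(0, P * P, J)
      for (r in seq_len(P)) for (s in seq_len(P))
        out[(s - 1L) * P + r, ] <- Psi[, r] * Psi[, s] / den
      out
    })
  } else {
    stop("grid assembly requires a 'known' or 'normal' uncertainty model",
         call. = FALSE)
  }
}

#' Assemble block information matrices over a design grid
#'
#' Riemann assembly: for item i, \eqn{M_i = \sum_j E_i(t_j)\, w_{ji}\,
#' h_{tot}(t_j)\, (\theta_{j+1}-\theta_j)} where \eqn{E_i(t_j)} is the
#' elemental information at midpoint \eqn{t_j} under the uncertainty model
#' (point prior for `"known"`, `N(t_j, 1/I(t_j))` for `"normal"`), and
#' \eqn{w_{ji}} is the design weight of cell j for item i.
#'
#' @param items Calibration [item_bank()].
#' @param design A [random_design()] or [optimize_design()] result.
#' @param grid The [build_grid()] the design lives on (defaults to the
#'   design's own grid).
#' @param uncertainty An [uncertainty_model()] of kind `"known"` or
#'   `"normal"`.
#' @param nodes Gauss-Hermite node count for the inner integral.
#' @return A [block_info()] with one block per calibration item.
#' @export
assemble_from_grid <- function(items, design, grid = design$grid,
                               uncertainty = uncertainty_model("known"),
                               nodes = .GH_NODES) {
  stopifnot(inherits(design, "calib_design"))
  if (nrow(design$weights) != grid$J || ncol(design$weights) != length(items))
    stop("design dimensions do not match grid/items", call. = FALSE)
  elems <- .elemental_grid(items, grid, uncertainty, nodes)
  .assemble(elems, design$weights, grid, items)
}

.assemble <- function(elems, weights, grid, items) {
  mass <- grid$htot * grid$step
  blocks <- lapply(seq_along(items), function(i) {
    p <- .npar(items[[i]])
    m <- matrix(drop(elems[[i]] %*% (weights[, i] * mass)), p, p)
    (m + t(m)) / 2
  })
  block_info(blocks)
}

#' Assemble block information matrices from examinee posterior draws
#'
#' Monte-Carlo/Riemann assembly when no distributional assumption is made:
#' sort the ability estimates, form midpoints \eqn{\tilde t_j =
#' (\hat\theta_j + \hat\theta_{j+1})/2} and spacings, and accumulate each
#' examinee's draw-based elemental information weighted by the standard
#' normal density of the population of estimates at \eqn{\tilde t_j}.  The
#' N-1 available spacings form the Riemann sum.
#'
#' @param items Calibration [item_bank()].
#' @param design A 0/1 or fractional design whose cell containing
#'   \eqn{\tilde t_j} supplies the allocation weight.
#' @param theta_hats Ability estimates, one per examinee (any order).
#' @param draw_sets List of [ability_prior()] objects of kind `"draws"`,
#'   aligned with `theta_hats`.
#' @return A [block_info()].
#' @export
assemble_from_sample <- function(items, design, theta_hats, draw_sets) {
  N <- length(theta_hats)
  if (N < 2L) stop("at least two examinees are required", call. = FALSE)
  stopifnot(length(draw_sets) == N)
  ord <- order(theta_hats)
  th <- theta_hats[ord]
  draw_sets <- draw_sets[ord]
  grid <- design$grid
  tmid <- (th[-N] + th[-1L]) / 2
  dlt <- diff(th)
  hpop <- stats::dnorm(tmid)
  cells <- pmin(pmax(floor((tmid - grid$boundaries[1L]) / grid$step) + 1L,
                     1L), grid$J)
  blocks <- lapply(items, function(item) {
    p <- .npar(item)
    matrix(0, p, p)
  })
  for (j in seq_len(N - 1L)) {
    ds <- draw_sets[[j]]
    for (i in seq_along(items)) {
      w <- design$weights[cells[j], i]
      if (w <= 0) next
      blocks[[i]] <- blocks[[i]] +
        elemental_info_uncertain(items[[i]], ds) * (w * hpop[j] * dlt[j])
    }
  }
  block_info(blocks)
}
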