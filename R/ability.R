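# Ability estimation from operational responses and the uncertainty model
# g(theta | theta_hat): asymptotic-normal approximation or posterior draws.

# ability search / quadrature domain: N(0,1) mass outside is < 2e-9
.THETA_LO <- -6
.THETA_HI <- 6

#' Ability uncertainty prior g(theta | theta_hat)
#'
#' Container for the three ways the package quantifies what is known about a
#' true ability: a degenerate point (`"point"`, the known-ability limit), an
#' asymptotic normal posterior (`"normal"`), or an empirical set of posterior
#' draws (`"draws"`).
#'
#' @param kind `"point"`, `"normal"` or `"draws"`.
#' @param mean Location (the ability estimate) for kinds `"point"`/`"normal"`.
#' @param variance Positive variance for kind `"normal"`.
#' @param draws Numeric vector of posterior draws for kind `"draws"`.
#' @return An object of class `"ability_prior"`.
#' @export
ability_prior <- function(kind = c("point", "normal", "draws"),
                          mean = NULL, variance = NULL, draws = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("point", "normal")) {
    if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean))
      stop("'mean' must be a single finite number", call. = FALSE)
  }
  if (kind == "normal") {
    if (!is.numeric(variance) || length(variance) != 1L ||
        !is.finite(variance) || variance <= 0)
      stop("'variance' must be a single positive number", call. = FALSE)
  }
  if (kind == "draws") {
    if (!is.numeric(draws) || !length(draws) || anyNA(draws))
      stop("'draws' must be a non-empty numeric vector", call. = FALSE)
  }
  structure(list(kind = kind, mean = mean, variance = variance, draws = draws),
            class = "ability_prior")
}

#' @export
print.ability_prior <- function(x, ...) {
  switch(x$kind,
    point  = cat(sprintf("<ability prior> point mass at %.4f\n", x$mean)),
    normal = cat(sprintf("<ability prior> N(%.4f, %.4f)\n", x$mean,
                         x$variance)),
    draws  = cat(sprintf("<ability prior> %d posterior draws (mean %.4f)\n",
                         length(x$draws), mean(x$draws))))
  invisible(x)
}

# Bernoulli log-likelihood of a response vector at ability values theta
.resp_loglik <- function(responses, bank, theta) {
  ll <- 0
  for (i in seq_along(bank)) {
    p <- prob(bank[[i]], theta)
    ll <- ll + responses[i] * log(p) + (1 - responses[i]) * log1p(-p)
  }
  ll
}

#' Maximum-likelihood ability estimate
#'
#' Safeguarded Newton (Fisher scoring) maximizer of the Bernoulli
#' log-likelihood over `[-6, 6]`.  All-correct and all-incorrect response
#' patterns have a monotone likelihood and are clamped to the boundary.
#'
#' @param responses 0/1 vector, one entry per bank item.
#' @param bank The operational [item_bank()].
#' @param tol Convergence tolerance on the score step.
#' @param max_iter Maximum Newton iterations before the grid-search fallback.
#' @return The MLE \eqn{\hat\theta}, a single number in `[-6, 6]`.
#' @export
estimate_ability_mle <- function(responses, bank, tol = 1e-10,
                                 max_iter = 100L) {
  responses <- as.numeric(responses)
  stopifnot(length(responses) == length(bank), all(responses %in% c(0, 1)))
  if (all(responses == 1)) return(.THETA_HI)
  if (all(responses == 0)) return(.THETA_LO)
  theta <- 0
  for (it in seq_len(max_iter)) {
    score <- 0; info <- 0
    for (i in seq_along(bank)) {
      itc <- bank[[i]]
      p <- prob(itc, theta)
      dp <- .dprob_dtheta(itc, theta)
      score <- score + (responses[i] - p) * dp / (p * (1 - p))
      info <- info + dp^2 / (p * (1 - p))
    }
    step <- score / info
    theta <- min(max(theta + step, .THETA_LO), .THETA_HI)
    if (abs(step) < tol || theta %in% c(.THETA_LO, .THETA_HI) && it > 1)
      return(theta)
  }
  # fallback: coarse grid + local refinement
  grid <- seq(.THETA_LO, .THETA_HI, length.out = 601L)
  ll <- .resp_loglik(responses, bank, grid)
  stats::optimize(function(t) .resp_loglik(responses, bank, t),
                  interval = c(max(.THETA_LO, grid[which.max(ll)] - 0.05),
                               min(.THETA_HI, grid[which.max(ll)] + 0.05)),
                  maximum = TRUE, tol = tol)$maximum
}

#' Asymptotic normal ability posterior
#'
#' The normal approximation \eqn{g(\theta|\hat\theta) =
#' N(\hat\theta, I^{-1}(\hat\theta))}, with \eqn{I} the test information of
#' the operational bank.
#'
#' @param theta_hat Ability estimate.
#' @param bank The operational [item_bank()].
#' @return An [ability_prior()] of kind `"normal"`.
#' @export
normal_posterior <- function(theta_hat, bank) {
  info <- test_information(bank, theta_hat)
  if (!is.finite(info) || info <= 0)
    stop("operational test information is zero at theta_hat = ", theta_hat,
         call. = FALSE)
  ability_prior("normal", mean = theta_hat, variance = 1 / info)
}

#' Expected a posteriori (EAP) ability estimate
#'
#' Posterior mean of ability under a standard normal prior, computed by
#' fixed-grid quadrature on `[-6, 6]`.
#'
#' @inheritParams estimate_ability_mle
#' @param nodes Number of quadrature nodes (default 241, step .05).
#' @return The EAP estimate, a single finite number.
#' @export
eap_estimate <- function(responses, bank, nodes = 241L) {
  drop(.eap_matrix(matrix(as.numeric(responses), nrow = 1L), bank, nodes))
}

# vectorized EAP for an N x m response matrix (used by the simulation study)
.eap_matrix <- function(resp, bank, nodes = 241L) {
  grid <- seq(.THETA_LO, .THETA_HI, length.out = nodes)
  P <- vapply(bank, prob, numeric(nodes), theta = grid)   # nodes x m
  logpost <- resp %*% t(log(P)) + (1 - resp) %*% t(log1p(-P))
  logpost <- sweep(logpost, 2L, -stats::dnorm(grid, log = TRUE), `-`)
  logpost <- logpost - apply(logpost, 1L, max)
  w <- exp(logpost)
  as.numeric((w %*% grid) / rowSums(w))
}

#' Metropolis-Hastings posterior draws of ability
#'
#' Random-walk MH sampling from the ability posterior (standard normal prior
#' times Bernoulli likelihood).  The proposal is Gaussian with standard
#' deviation twice the approximate posterior s.d. (1.0 when the information
#' is zero); burn-in 500 iterations, no thinning.
#'
#' @inheritParams estimate_ability_mle
#' @param S Number of retained draws.
#' @param seed Optional integer seed for reproducibility.
#' @param burn_in Discarded initial iterations.
#' @return An [ability_prior()] of kind `"draws"` with `S` draws.  An
#'   acceptance rate outside \[0.1, 0.9\] triggers a warning.
#' @export
sample_posterior_mh <- function(responses, bank, S, seed = NULL,
                                burn_in = 500L) {
  stopifnot(S >= 1)
  responses <- as.numeric(responses)
  if (!is.null(seed)) set.seed(seed)
  start <- if (length(bank)) eap_estimate(responses, bank) else 0
  info <- if (length(bank)) test_information(bank, start) else 0
  prop_sd <- if (is.finite(info) && info > 0) 2 / sqrt(info + 1) else 1.0
  logpost <- function(t)
    stats::dnorm(t, log = TRUE) +
      if (length(bank)) .resp_loglik(responses, bank, t) else 0
  n_tot <- burn_in + S
  out <- numeric(n_tot)
  cur <- start; lp_cur <- logpost(cur); acc <- 0L
  steps <- stats::rnorm(n_tot, sd = prop_sd)
  us <- log(stats::runif(n_tot))
  for (s in seq_len(n_tot)) {
    cand <- cur + steps[s]
    lp_cand <- logpost(cand)
    if (us[s] < lp_cand - lp_cur) {
      cur <- cand; lp_cur <- lp_cand; acc <- acc + 1L
    }
    out[s] <- cur
  }
  rate <- acc / n_tot
  if (rate < 0.1 || rate > 0.9)
    warning(sprintf("MH acceptance rate %.2f outside [0.1, 0.9]", rate),
            call. = FALSE)
  ability_prior("draws", draws = out[(burn_in + 1L):n_tot])
}

#' Ability uncertainty model over the design space
#'
#' Maps a hypothetical ability estimate to an [ability_prior()].  Kind
#' `"known"` treats estimates as exact (the point prior); `"normal"` attaches
#' the asymptotic posterior `N(t, 1/I(t))` computed from an operational bank,
#' so designs can be derived before any examinee is tested; `"draws"` holds
#' per-examinee posterior draw sets and is consumed by
#' [assemble_from_sample()] after the operational test has been analysed.
#'
#' @param kind `"known"`, `"normal"` or `"draws"`.
#' @param op_bank Operational [item_bank()] (required for `"normal"`).
#' @param theta_hats Sorted-or-not ability estimates (kind `"draws"`).
#' @param draw_sets List of [ability_prior()] draw sets, one per examinee
#'   (kind `"draws"`).
#' @return An object of class `"uncertainty_model"`.
#' @export
uncertainty_model <- function(kind = c("known", "normal", "draws"),
                              op_bank = NULL, theta_hats = NULL,
                              draw_sets = NULL) {
  kind <- match.arg(kind)
  if (kind == "normal" && !inherits(op_bank, "item_bank"))
    stop("kind 'normal' requires an operational item bank", call. = FALSE)
  if (kind == "draws") {
    if (is.null(theta_hats) || is.null(draw_sets) ||
        length(theta_hats) != length(draw_sets))
      stop("kind 'draws' requires matching 'theta_hats' and 'draw_sets'",
           call. = FALSE)
  }
  structure(list(kind = kind, op_bank = op_bank, theta_hats = theta_hats,
                 draw_sets = draw_sets),
            class = "uncertainty_model")
}

#' @export
print.uncertainty_model <- function(x, ...) {
  cat(sprintf("<uncertainty model> kind = %s%s\n", x$kind,
              if (x$kind == "normal")
                sprintf(" (m = %d operational items)", length(x$op_bank))
              else if (x$kind == "draws")
                sprintf(" (%d examinees)", length(x$theta_hats))
              else ""))
  invisible(x)
}

# prior attached to a hypothetical ability estimate t
.prior_at <- function(um, t) {
  switch(um$kind,
         known  = ability_prior("point", mean = t),
         normal = normal_posterior(t, um$op_bank),
         stop("a 'draws' uncertainty model has no grid prior; ",
              "use assemble_from_sample()", call. = FALSE))
}
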