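# Relative D-, per-item D- and c/L-efficiencies between calibration designs.

#' Relative efficiency of one design versus another
#'
#' For the D-criterion, \eqn{RE_D = (\det M(h_1)/\det M(h_2))^{1/p}} with p
#' the total parameter count; the per-item efficiencies use each block's
#' determinant with its own parameter count, so the overall value is their
#' geometric mean (weighted by parameter counts).  A value above 1 means the
#' first design is better: the second needs \eqn{RE_D} times as many
#' examinees for the same precision.  For the L/c-criterion the per-item
#' efficiency is the variance-approximation ratio
#' \eqn{c^T M_i(h_2)^{-1} c \,/\, c^T M_i(h_1)^{-1} c} (trace form for
#' general L), and the overall value the ratio of summed traces.
#'
#' @param M1,M2 [block_info()] matrices of the two designs, assembled under
#'   the same evaluation uncertainty model.
#' @param criterion A `"design_criterion"`.
#' @param labels Length-2 character vector naming the designs.
#' @param items Calibration [item_bank()] (needed for per-item L matrices
#'   when the criterion carries more than one).
#' @return An object of class `"efficiency_report"` with fields `overall`,
#'   `per_item`, `criterion` and `labels`.
#' @export
relative_efficiency <- function(M1, M2, criterion = criterion_d(),
                                labels = c("design1", "design2"),
                                items = NULL) {
  stopifnot(length(M1$blocks) == length(M2$blocks))
  nblk <- length(M1$blocks)
  if (criterion$kind == "D") {
    ld1 <- vapply(M1$blocks, .logdet, numeric(1))
    ld2 <- vapply(M2$blocks, .logdet, numeric(1))
    if (any(!is.finite(ld1)) || any(!is.finite(ld2)))
      stop("singular information block; cannot compute D-efficiency",
           call. = FALSE)
    pk <- vapply(M1$blocks, nrow, integer(1))
    per_item <- exp((ld1 - ld2) / pk)
    overall <- exp(sum(ld1 - ld2) / sum(pk))
  } else {
    L <- if (length(criterion$L) == 1L) rep(criterion$L, nblk)
         else if (!is.null(items)) .l_matrices(criterion, items)
         else criterion$L
    if (length(L) != nblk)
      stop("criterion must supply one L matrix per block", call. = FALSE)
    tr1 <- vapply(seq_len(nblk), function(i)
      sum(diag(solve(M1$blocks[[i]], L[[i]]))), numeric(1))
    tr2 <- vapply(seq_len(nblk), function(i)
      sum(diag(solve(M2$blocks[[i]], L[[i]]))), numeric(1))
    per_item <- tr2 / tr1
    overall <- sum(tr2) / sum(tr1)
  }
  structure(list(overall = overall, per_item = per_item,
                 criterion = criterion$kind, labels = labels),
            class = "efficiency_report")
}

#' @export
print.efficiency_report <- function(x, ...) {
  cat(sprintf("<%s-efficiency> %s vs %s\n", x$criterion, x$labels[1L],
              x$labels[2L]))
  tab <- c(x$per_item, overall = x$overall)
  names(tab)[seq_along(x$per_item)] <-
    paste0("item", seq_along(x$per_item))
  print(round(tab, 2))
  invisible(x)
}

#' Run a named design-efficiency comparison
#'
#' Builds two designs for a calibration block given an operational test of
#' `m` items (discrimination `a_op`, difficulties equidistant on
#' `[-1.5, 1.5]`), assembles both information matrices under the same
#' evaluation uncertainty model -- the m-item normal model, or the
#' known-ability model when `m` is infinite -- and reports their relative
#' efficiency.  Design labels:
#' \describe{
#'   \item{`"uncertainty"`}{D-optimal under the m-item normal uncertainty
#'     model (coincides with `"known"` when `m = Inf`).}
#'   \item{`"known"`}{D-optimal pretending abilities are known.}
#'   \item{`"random"`}{equal 1/n allocation.}
#' }
#'
#' @param calib Calibration [item_bank()].
#' @param m Number of operational items; `Inf` for known abilities.
#' @param a_op Operational discrimination (default 1).
#' @param design_a,design_b Design labels compared as a vs b.
#' @param criterion Efficiency criterion (default D).
#' @param grid A [build_grid()].
#' @param nodes Gauss-Hermite node count.
#' @return An `"efficiency_report"`.
#' @export
efficiency_experiment <- function(calib, m, a_op = 1,
                                  design_a = "uncertainty",
                                  design_b = "random",
                                  criterion = criterion_d(),
                                  grid = build_grid(), nodes = .GH_NODES) {
  eval_model <- if (is.infinite(m)) uncertainty_model("known")
                else uncertainty_model("normal",
                                       make_operational_test(m, a_op))
  build <- function(label) {
    switch(label,
      uncertainty = optimize_design(calib, grid, eval_model, nodes = nodes),
      known = optimize_design(calib, grid, uncertainty_model("known"),
                              nodes = nodes),
      random = random_design(length(calib), grid),
      stop("unknown design label: ", label, call. = FALSE))
  }
  da <- build(design_a)
  db <- build(design_b)
  Ma <- assemble_from_grid(calib, da, grid, eval_model, nodes)
  Mb <- assemble_from_grid(calib, db, grid, eval_model, nodes)
  relative_efficiency(Ma, Mb, criterion, labels = c(design_a, design_b),
                      items = calib)
}
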