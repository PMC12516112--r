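# Item response functions, item/test information and link gradients for the
# 2PL and 3PL logistic models.

# exponent clamp: keeps the logistic monotone and NaN-free for extreme inputs
.EXP_CLAMP <- 700

.logistic <- function(x) 1 / (1 + exp(-pmin(pmax(x, -.EXP_CLAMP), .EXP_CLAMP)))

#' Create a single IRT item
#'
#' An item under the two- or three-parameter logistic model.  The 2PL model is
#' \eqn{p(\theta) = 1/(1 + e^{-a(\theta - b)})}; the 3PL model adds a lower
#' asymptote \eqn{c}: \eqn{p(\theta) = c + (1-c)/(1 + e^{-a(\theta - b)})}.
#'
#' @param a Discrimination, a positive number.
#' @param b Difficulty, a real number.
#' @param c Guessing (lower asymptote) in \[0, 1); `NULL` for 2PL items.
#' @param model `"2PL"` or `"3PL"`.  Defaults to `"3PL"` when `c` is supplied.
#' @return An object of class `"irt_item"`.
#' @examples
#' it <- irt_item(a = 1.6, b = -1)
#' prob(it, 0)
#' @export
irt_item <- function(a, b, c = NULL,
                     model = if (is.null(c)) "2PL" else "3PL") {
  model <- match.arg(model, c("2PL", "3PL"))
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a) || a <= 0)
    stop("'a' (discrimination) must be a single positive number", call. = FALSE)
  if (!is.numeric(b) || length(b) != 1L || !is.finite(b))
    stop("'b' (difficulty) must be a single finite number", call. = FALSE)
  if (model == "3PL") {
    if (is.null(c) || !is.numeric(c) || length(c) != 1L || is.na(c) ||
        c < 0 || c >= 1)
      stop("3PL items require a guessing parameter 'c' in [0, 1)",
           call. = FALSE)
  } else {
    if (!is.null(c) && !isTRUE(all.equal(c, 0)))
      stop("'c' must be absent (or 0) for a 2PL item", call. = FALSE)
    c <- NULL
  }
  structure(list(model = model, a = a, b = b, c = c), class = "irt_item")
}

#' @export
print.irt_item <- function(x, ...) {
  cat(sprintf("<%s item>  a = %g, b = %g%s\n", x$model, x$a, x$b,
              if (x$model == "3PL") sprintf(", c = %g", x$c) else ""))
  invisible(x)
}

# number of item parameters (2 for 2PL, 3 for 3PL)
.npar <- function(item) if (item$model == "3PL") 3L else 2L

#' Create an item bank
#'
#' @param items A list of [irt_item()] objects, or a data frame with columns
#'   `model`, `a`, `b` and optionally `c` (empty/`NA` for 2PL rows).
#' @param role `"calibration"` or `"operational"`.
#' @return An object of class `"item_bank"`: a list of items with a role
#'   attribute.  Item indices are 1-based and follow the input order.
#' @export
item_bank <- function(items, role = c("calibration", "operational")) {
  role <- match.arg(role)
  if (is.data.frame(items)) {
    items <- lapply(seq_len(nrow(items)), function(i) {
      row <- items[i, , drop = FALSE]
      cc <- if ("c" %in% names(row) && !is.na(row$c) && row$c != "")
        as.numeric(row$c) else NULL
      mdl <- if ("model" %in% names(row)) as.character(row$model)
             else if (is.null(cc)) "2PL" else "3PL"
      tryCatch(irt_item(as.numeric(row$a), as.numeric(row$b), cc, mdl),
               error = function(e)
                 stop(sprintf("item row %d: %s", i, conditionMessage(e)),
                      call. = FALSE))
    })
  }
  if (!length(items)) stop("an item bank must contain at least one item",
                           call. = FALSE)
  if (!all(vapply(items, inherits, logical(1), "irt_item")))
    stop("'items' must all be irt_item objects", call. = FALSE)
  structure(items, role = role, class = "item_bank")
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item bank>  %d %s item(s)\n", length(x), attr(x, "role")))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.item_bank <- function(x, ...) {
  data.frame(
    item  = seq_along(x),
    model = vapply(x, `[[`, character(1), "model"),
    a     = vapply(x, `[[`, numeric(1), "a"),
    b     = vapply(x, `[[`, numeric(1), "b"),
    c     = vapply(x, function(it) if (is.null(it$c)) NA_real_ else it$c,
                   numeric(1))
  )
}

#' Read an item bank from CSV
#'
#' Expects a header `model,a,b,c` (the `c` column may be empty for 2PL rows);
#' one row per item, row order defining the 1-based item index.
#'
#' @param path Path to a CSV file.
#' @param role Bank role, passed to [item_bank()].
#' @return An `"item_bank"`.
#' @export
read_item_bank <- function(path, role = c("calibration", "operational")) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!nrow(df)) stop("empty item bank file: ", path, call. = FALSE)
  need <- c("a", "b")
  if (!all(need %in% names(df)))
    stop("item bank CSV must have columns 'model,a,b[,c]'", call. = FALSE)
  item_bank(df, role = match.arg(role))
}

#' Write an item bank to CSV
#'
#' @param bank An `"item_bank"`.
#' @param path Output path.
#' @export
write_item_bank <- function(bank, path) {
  df <- as.data.frame(bank)[, c("model", "a", "b", "c")]
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Probability of a correct response
#'
#' @param item An [irt_item()].
#' @param theta Ability value(s).
#' @return `P(Y = 1 | theta)`, vectorized over `theta`.
#' @export
prob <- function(item, theta) {
  p0 <- .logistic(item$a * (theta - item$b))
  if (item$model == "3PL") item$c + (1 - item$c) * p0 else p0
}

#' Fisher item information
#'
#' For the 2PL model \eqn{I(\theta) = a^2 p (1-p)}; for the 3PL model
#' \eqn{I(\theta) = a^2 (1-p)(p-c)^2 / (p (1-c)^2)}.
#'
#' @inheritParams prob
#' @return Nonnegative information value(s), vectorized over `theta`.
#' @export
item_information <- function(item, theta) {
  p <- prob(item, theta)
  if (item$model == "3PL") {
    item$a^2 * (1 - p) * (p - item$c)^2 / (p * (1 - item$c)^2)
  } else {
    item$a^2 * p * (1 - p)
  }
}

#' Test information of an item bank
#'
#' Sum of [item_information()] over the bank's items.
#'
#' @param bank An [item_bank()].
#' @param theta Ability value(s).
#' @export
test_information <- function(bank, theta) {
  Reduce(`+`, lapply(bank, item_information, theta = theta))
}

# derivative of p wrt theta (used by ability estimation)
.dprob_dtheta <- function(item, theta) {
  p <- prob(item, theta)
  if (item$model == "3PL") {
    item$a * (p - item$c) * (1 - p) / (1 - item$c)
  } else {
    item$a * p * (1 - p)
  }
}

# derivative of p wrt the item parameter vector; rows = length(theta),
# cols = npar.  2PL: p(1-p) * (theta-b, -a).  3PL first two components carry
# the (p-c)(1-p)/(1-c) factor; third is dp/dc = (1-p)/(1-c).
.dprob_dzeta <- function(item, theta) {
  p <- prob(item, theta)
  if (item$model == "3PL") {
    f <- (p - item$c) * (1 - p) / (1 - item$c)
    cbind((theta - item$b) * f, -item$a * f, (1 - p) / (1 - item$c))
  } else {
    pq <- p * (1 - p)
    cbind((theta - item$b) * pq, -item$a * pq)
  }
}

#' Gradient of the logit link in the item parameters
#'
#' Returns \eqn{\partial\eta/\partial\zeta} evaluated at `theta`, the
#' linearization vector of the logistic model: `(theta - b, -a)` for a 2PL
#' item, and the 3PL analogue (which reduces to the 2PL vector plus a
#' guessing component as `c -> 0`).  The elemental information matrix under
#' known abilities is `p(1-p)` times the outer product of this vector.
#'
#' @param item An [irt_item()].
#' @param theta A single ability value.
#' @return A numeric vector of length 2 (2PL) or 3 (3PL).
#' @export
eta_gradient <- function(item, theta) {
  stopifnot(length(theta) == 1L)
  p <- prob(item, theta)
  drop(.dprob_dzeta(item, theta)) / (p * (1 - p))
}
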