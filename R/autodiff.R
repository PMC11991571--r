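# Minimal define-by-run reverse-mode autodiff tape.
#
# A tensor is an environment holding a numeric array (`value`), an optional
# accumulated gradient (`grad`), and — when recorded on the tape — its parent
# tensors plus a closure mapping the output gradient to parent gradients.
# Topological order for the backward sweep comes from a monotone creation id.

.wn <- new.env(parent = emptyenv())
.wn$counter <- 0L
.wn$grad_enabled <- TRUE

wn_next_id <- function() {
  .wn$counter <- .wn$counter + 1L
  .wn$counter
}

#' Create a tensor node
#'
#' @param value numeric array (any shape; scalars are length-1 vectors).
#' @param requires_grad logical; parameters set this to `TRUE` so the
#'   optimizer can find them.
#' @return a `wn_tensor` environment.
#' @keywords internal
new_tensor <- function(value, requires_grad = FALSE) {
  t <- new.env(parent = emptyenv())
  t$value <- value
  t$grad <- NULL
  t$requires_grad <- requires_grad
  t$parents <- NULL
  t$backward_fn <- NULL
  t$id <- wn_next_id()
  class(t) <- "wn_tensor"
  t
}

is_tensor <- function(x) inherits(x, "wn_tensor")

# Record an op result on the tape (unless gradient recording is disabled).
# `backward_fn(grad_out)` must return a list of gradients, one per parent
# (NULL entries are skipped).
make_op <- function(value, parents, backward_fn) {
  t <- new_tensor(value)
  if (isTRUE(.wn$grad_enabled)) {
    t$parents <- parents
    t$backward_fn <- backward_fn
  }
  t
}

#' Evaluate an expression without recording gradients
#' @param expr expression to evaluate.
#' @keywords internal
with_no_grad <- function(expr) {
  old <- .wn$grad_enabled
  .wn$grad_enabled <- FALSE
  on.exit(.wn$grad_enabled <- old)
  force(expr)
}

#' Reverse-mode backward sweep from a scalar loss tensor
#'
#' Accumulates gradients into every tensor reachable from `loss` through
#' recorded ops. Gradients add across multiple uses of the same tensor.
#' @param loss a scalar `wn_tensor`.
#' @keywords internal
backward <- function(loss) {
  stopifnot(is_tensor(loss), length(loss$value) == 1L)
  # collect reachable nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(loss)
  nodes <- list()
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$id)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$id, integer(1)), decreasing = TRUE)
  loss$grad <- 1
  for (nd in nodes[ord]) {
    if (is.null(nd$backward_fn) || is.null(nd$grad)) next
    gs <- nd$backward_fn(nd$grad)
    for (k in seq_along(nd$parents)) {
      g <- gs[[k]]
      if (is.null(g)) next
      p <- nd$parents[[k]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(loss)
}

# zero the gradients of a list of tensors
zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

#' Run an expression with a temporary RNG seed, restoring the RNG state after
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
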