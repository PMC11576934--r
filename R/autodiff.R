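# Minimal reverse-mode autodiff tape.
#
# Nodes are environments recorded on a tape in creation order (a valid
# topological order); backward() walks the tape in reverse, calling each
# node's bwd closure with the accumulated output gradient and adding the
# returned pieces onto the parents. Leaves carry parameters; their grads
# are read off after backward. Every layer gradient is checked against
# numerical differentiation in the test suite.

.tapeNew <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

.tapeNode <- function(tape, value, parents = list(), bwd = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$parents <- parents
  nd$bwd <- bwd
  n <- tape$n + 1L
  if (n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[n]] <- nd
  tape$n <- n
  nd
}

.tapeLeaf <- function(tape, value) .tapeNode(tape, value)

.tapeBackward <- function(tape, root, seed = 1) {
  root$grad <- seed
  for (i in seq(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (is.null(nd$grad) || is.null(nd$bwd)) next
    gs <- nd$bwd(nd$grad)
    ps <- nd$parents
    for (j in seq_along(ps)) {
      g <- gs[[j]]
      if (is.null(g)) next
      p <- ps[[j]]
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
    nd$grad <- NULL # free memory as we go
  }
  invisible(NULL)
}
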