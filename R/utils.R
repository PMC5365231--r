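# Internal helpers: deterministic tie order and a binary min-heap.
#
# The global tie order on paths is (internal cost, number of edges,
# lexicographic node-identifier sequence).  Lexicographic comparison uses
# C-locale (radix) byte order so results do not depend on the session locale.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
ksp_stop <- function(fmt, ..., class = "kspathway_error") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "error", "condition")))
}

#' @noRd
ksp_warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# rank of each node name under C-locale sort; unique names assumed
#' @noRd
lex_ranks <- function(nodes) {
  match(nodes, sort(nodes, method = "radix"))
}

# elementwise lexicographic "a < b" on integer rank vectors; shorter prefix wins
#' @noRd
lex_less_idx <- function(a, b) {
  m <- min(length(a), length(b))
  if (m > 0L) {
    d <- which(a[seq_len(m)] != b[seq_len(m)])
    if (length(d)) return(a[d[1L]] < b[d[1L]])
  }
  length(a) < length(b)
}

# full tie-order comparison: is path A strictly before path B?
# costs compared exactly as doubles (no epsilon) by design.
#' @noRd
tie_before <- function(cost_a, lexr_a, cost_b, lexr_b) {
  if (cost_a != cost_b) return(cost_a < cost_b)
  if (length(lexr_a) != length(lexr_b)) return(length(lexr_a) < length(lexr_b))
  lex_less_idx(lexr_a, lexr_b)
}

# Binary min-heap keyed by a double, carrying an integer payload.
# Closure-based; supports lazy (duplicate) pushes.
#' @noRd
new_min_heap <- function(capacity = 64L) {
  keys <- numeric(capacity)
  vals <- integer(capacity)
  n <- 0L

  push <- function(key, val) {
    if (n == length(keys)) {
      keys[2L * n] <<- 0
      vals[2L * n] <<- 0L
    }
    n <<- n + 1L
    i <- n
    keys[i] <<- key
    vals[i] <<- val
    while (i > 1L) {
      p <- i %/% 2L
      if (keys[p] <= keys[i]) break
      kt <- keys[p]; keys[p] <<- keys[i]; keys[i] <<- kt
      vt <- vals[p]; vals[p] <<- vals[i]; vals[i] <<- vt
      i <- p
    }
    invisible(NULL)
  }

  pop <- function() {
    if (n == 0L) return(NULL)
    out <- c(keys[1L], vals[1L])
    keys[1L] <<- keys[n]
    vals[1L] <<- vals[n]
    n <<- n - 1L
    i <- 1L
    repeat {
      l <- 2L * i; r <- l + 1L; s <- i
      if (l <= n && keys[l] < keys[s]) s <- l
      if (r <= n && keys[r] < keys[s]) s <- r
      if (s == i) break
      kt <- keys[s]; keys[s] <<- keys[i]; keys[i] <<- kt
      vt <- vals[s]; vals[s] <<- vals[i]; vals[i] <<- vt
      i <- s
    }
    out
  }

  list(
    push = push,
    pop = pop,
    peek_key = function() if (n > 0L) keys[1L] else Inf,
    size = function() n
  )
}
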