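#' Build the weighted digraph of a square matrix
#'
#' Interprets \code{M} (in practice the squared Jacobian \eqn{J^2}) as the
#' adjacency matrix of a directed graph: an edge \eqn{i \to j} exists
#' whenever \eqn{|M_{ji}|} exceeds \code{zeroTol} relative to the largest
#' entry, and carries weight \eqn{M_{ji}}.  Self-loops appear for every
#' nonzero diagonal entry; sign information lives in the weight.
#'
#' @param M square numeric matrix
#' @param zeroTol relative zero tolerance (0 for exact input)
#' @return an \linkS4class{InteractionGraph}
#' @examples
#' g <- interactionGraph(squaredJacobian(
#'   autocatalyticNetwork(3, 1, 0.1, 0.1)))
#' length(enumerateCycles(g))   # 8
#' @export
interactionGraph <- function(M, zeroTol = 1e-12) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("matrix must be square")
  s <- max(abs(M))
  W <- t(M)                      # weights[i, j] = M[j, i] = weight of i -> j
  if (s > 0) W[abs(W) <= zeroTol * s] <- 0
  new("InteractionGraph", n = nrow(M), weights = W, matrix = M)
}

setMethod("show", "InteractionGraph", function(object) {
  ne <- sum(object@weights != 0)
  cat(sprintf("InteractionGraph: %d vertices, %d weighted edges (%d self-loops)\n",
              object@n, ne, sum(diag(object@weights) != 0)))
})

#' Enumerate all simple directed cycles
#'
#' Finds every simple directed cycle (including self-loops) of the graph,
#' in canonical form: the vertex sequence starts at its smallest vertex and
#' preserves direction, so \code{1,2,3} and \code{1,3,2} are distinct
#' cycles.  Enumeration is depth-first with the smallest cycle vertex as
#' anchor, which is adequate for the dense graphs of squared Jacobians up
#' to roughly eight vertices (factor finding, not cycle finding, is the
#' practical bottleneck).
#'
#' @param g an \linkS4class{InteractionGraph}
#' @return list of cycles, each a list with \code{vertices} (integer
#'   vector), \code{length}, and \code{weight} (product of edge weights);
#'   ordered by length then lexicographically
#' @export
enumerateCycles <- function(g) {
  stopifnot(is(g, "InteractionGraph"))
  W <- g@weights
  n <- g@n
  adj <- lapply(seq_len(n), function(i) which(W[i, ] != 0))
  cycles <- list()
  for (s in seq_len(n)) {
    ## paths anchored at s, all other vertices > s
    path <- integer(0L)
    onPath <- logical(n)
    dfs <- function(v) {
      path[length(path) + 1L] <<- v
      onPath[v] <<- TRUE
      for (u in adj[[v]]) {
        if (u == s) {
          w <- 1
          vs <- path
          for (k in seq_along(vs)) {
            frm <- vs[k]
            to <- if (k < length(vs)) vs[k + 1L] else vs[1L]
            w <- w * W[frm, to]
          }
          cycles[[length(cycles) + 1L]] <<-
            list(vertices = vs, length = length(vs), weight = w)
        } else if (u > s && !onPath[u]) {
          dfs(u)
        }
      }
      onPath[v] <<- FALSE
      path <<- path[-length(path)]
    }
    dfs(s)
  }
  key <- vapply(cycles, function(cl)
    sprintf("%02d|%s", cl$length,
            paste(sprintf("%03d", cl$vertices), collapse = ",")),
    character(1L))
  cycles[order(key)]
}

#' Enumerate factors of degree k
#'
#' A factor of degree \code{k} is a set of pairwise vertex-disjoint simple
#' cycles jointly covering exactly \code{k} vertices; its cardinality is
#' the number of cycles it contains.  Factors are built by recursion over
#' the cycle list in a fixed order, so each factor appears exactly once.
#'
#' @param g an \linkS4class{InteractionGraph}
#' @param k target degree, between 1 and the number of vertices
#' @param cycles optional precomputed result of [enumerateCycles()]
#' @return list of factors, each a list with \code{cycles} (list of vertex
#'   vectors), \code{degree}, \code{cardinality} and \code{weight}
#'   (product of the member cycles' weights)
#' @export
enumerateFactors <- function(g, k, cycles = NULL) {
  stopifnot(is(g, "InteractionGraph"))
  k <- as.integer(k)
  if (k < 1L || k > g@n) stop("'k' must be between 1 and ", g@n)
  if (is.null(cycles)) cycles <- enumerateCycles(g)
  lens <- vapply(cycles, `[[`, integer(1L), "length")
  out <- list()
  used <- logical(g@n)
  pick <- function(start, remaining, chosen) {
    if (remaining == 0L) {
      w <- prod(vapply(chosen, `[[`, numeric(1L), "weight"))
      out[[length(out) + 1L]] <<- list(
        cycles = lapply(chosen, `[[`, "vertices"),
        degree = k, cardinality = length(chosen), weight = w)
      return(invisible())
    }
    if (start > length(cycles)) return(invisible())
    for (i in start:length(cycles)) {
      if (lens[i] > remaining) next
      vs <- cycles[[i]]$vertices
      if (any(used[vs])) next
      used[vs] <<- TRUE
      pick(i + 1L, remaining - lens[i], c(chosen, cycles[i]))
      used[vs] <<- FALSE
    }
  }
  pick(1L, k, list())
  out
}

#' Characteristic-polynomial coefficient from factors
#'
#' The coefficient \eqn{a_k} of \eqn{x^{n-k}} in \eqn{\det(xI + A)} is a
#' signed sum over the degree-\eqn{k} factors \eqn{f_k} of the graph of
#' \eqn{A}:
#' \deqn{a_k = \sum_{f_k} (-1)^{k - |f_k|} \prod_{c \in f_k} A[c],}
#' where \eqn{A[c]} is the product of edge weights around the cycle
#' \eqn{c}.  In particular \eqn{a_1 = \mathrm{Tr}(A)} and
#' \eqn{a_n = \det(A)}.  The sign convention is pinned by the test-suite
#' identity with direct determinant expansion.
#'
#' @param g an \linkS4class{InteractionGraph}
#' @param k coefficient index, 1..n
#' @param cycles optional precomputed cycle list
#' @return numeric coefficient
#' @export
coefficientViaFactors <- function(g, k, cycles = NULL) {
  facs <- enumerateFactors(g, k, cycles = cycles)
  if (!length(facs)) return(0)
  sum(vapply(facs, function(f)
    (-1)^(f$degree - f$cardinality) * f$weight, numeric(1L)))
}

#' Assemble det(xI + A) from the graph
#'
#' Full polynomial from [coefficientViaFactors()] for \eqn{k = 1, \ldots,
#' n} with leading coefficient 1.  Applied to the graph of \eqn{J^2} this
#' reproduces [rPolynomial()].
#'
#' @param g an \linkS4class{InteractionGraph}
#' @return a \linkS4class{Poly}
#' @examples
#' g <- interactionGraph(squaredJacobian(matrix(c(-1, -2, 2, -1), 2)))
#' charPolyViaGraph(g)   # x^2 - 6x + 25
#' @export
charPolyViaGraph <- function(g) {
  stopifnot(is(g, "InteractionGraph"))
  cycles <- enumerateCycles(g)
  a <- vapply(seq_len(g@n), function(k)
    coefficientViaFactors(g, k, cycles = cycles), numeric(1L))
  Poly(c(1, a))
}

#' Export a graph in DOT format
#' @param g an \linkS4class{InteractionGraph}
#' @param file optional path; when NULL the DOT text is returned
#' @return character vector of DOT lines (invisibly when written to file)
#' @export
graphAsDot <- function(g, file = NULL) {
  stopifnot(is(g, "InteractionGraph"))
  idx <- which(g@weights != 0, arr.ind = TRUE)
  lines <- c("digraph J2 {",
             sprintf("  %d -> %d [label=\"%.6g\"];",
                     idx[, 1L], idx[, 2L],
                     g@weights[idx]),
             "}")
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Cycle and factor listing as a list (JSON-ready)
#' @param g an \linkS4class{InteractionGraph}
#' @return list with elements \code{cycles} and \code{factors} (the latter
#'   indexed by degree)
#' @export
graphReport <- function(g) {
  cycles <- enumerateCycles(g)
  facs <- lapply(seq_len(g@n), function(k) {
    lapply(enumerateFactors(g, k, cycles = cycles), function(f)
      list(cycles = f$cycles, cardinality = f$cardinality,
           weight = f$weight))
  })
  names(facs) <- as.character(seq_len(g@n))
  list(n_vertices = g@n,
       cycles = lapply(cycles, function(cl)
         list(vertices = cl$vertices, length = cl$length,
              weight = cl$weight)),
       factors = facs)
}
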