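## J^2 of the three-species autocatalytic network (generic parameters):
## the worked dense example used throughout.
n3graph <- function(r = 1, alpha = 0.1, beta = 0.1) {
  interactionGraph(squaredJacobian(autocatalyticNetwork(3, r, alpha, beta)))
}

test_that("graph construction follows the J^2 adjacency conventions", {
  g <- interactionGraph(diag(c(1, 2, 3)))
  expect_equal(sum(g@weights != 0), 3L)               # self-loops only
  expect_equal(diag(g@weights), c(1, 2, 3))

  g0 <- interactionGraph(matrix(0, 3, 3))
  expect_equal(sum(g0@weights != 0), 0L)

  ## edge i -> j iff M[j, i] != 0, weight M[j, i]
  M <- matrix(0, 2, 2); M[2, 1] <- 5
  g2 <- interactionGraph(M)
  expect_equal(g2@weights[1, 2], 5)                   # edge 1 -> 2
  expect_equal(g2@weights[2, 1], 0)

  ## dense worked case: complete graph with self-loops, 9 edges
  expect_equal(sum(n3graph()@weights != 0), 9L)
})

test_that("the three-species graph has the known cycle inventory", {
  cycles <- enumerateCycles(n3graph())
  expect_length(cycles, 8L)
  lens <- vapply(cycles, `[[`, integer(1L), "length")
  expect_equal(sum(lens == 1L), 3L)                   # self-loops
  expect_equal(sum(lens == 2L), 3L)                   # {1,2}, {1,3}, {2,3}
  expect_equal(sum(lens == 3L), 2L)                   # {1,2,3} and {3,2,1}
  ## canonical form: starts at the minimum vertex, direction preserved
  three <- lapply(cycles[lens == 3L], `[[`, "vertices")
  expect_true(all(vapply(three, function(v) v[1L] == 1L, logical(1L))))
  expect_setequal(vapply(three, paste, character(1L), collapse = ","),
                  c("1,2,3", "1,3,2"))
})

test_that("cycle enumeration matches brute force on random digraphs", {
  set.seed(31)
  for (k in 1:8) {
    n <- sample(3:5, 1L)
    M <- matrix(rnorm(n * n), n)
    if (k %% 2L == 0L) M[matrix(runif(n * n) < 0.4, n)] <- 0  # sparsify
    g <- interactionGraph(M)
    got <- enumerateCycles(g)
    want <- bruteCycles(g@weights)
    expect_equal(length(got), length(want))
    expect_setequal(
      vapply(got, function(cl) paste(cl$vertices, collapse = ","),
             character(1L)),
      vapply(want, paste, character(1L), collapse = ","))
    ## weights are the product of edge weights around the cycle
    for (cl in got) {
      vs <- cl$vertices
      expect_equal(cl$weight,
                   prod(g@weights[cbind(vs, c(vs[-1L], vs[1L]))]))
    }
  }
})

test_that("factor enumeration reproduces the three-species factor table", {
  g <- n3graph()
  cycles <- enumerateCycles(g)

  f1 <- enumerateFactors(g, 1L, cycles)
  expect_length(f1, 3L)                               # the three self-loops
  expect_true(all(vapply(f1, `[[`, integer(1L), "cardinality") == 1L))

  f2 <- enumerateFactors(g, 2L, cycles)
  expect_length(f2, 6L)
  card <- vapply(f2, `[[`, integer(1L), "cardinality")
  expect_equal(sum(card == 1L), 3L)                   # single 2-cycles
  expect_equal(sum(card == 2L), 3L)                   # pairs of self-loops

  f3 <- enumerateFactors(g, 3L, cycles)
  sig <- vapply(f3, function(f)
    paste(sort(vapply(f$cycles, paste, character(1L), collapse = "-")),
          collapse = "|"), character(1L))
  expect_true("1-2-3" %in% sig)                       # {{1,2,3}}, |f| = 1
  expect_true("1|2|3" %in% sig)                       # {{1},{2},{3}}, |f| = 3
  expect_equal(vapply(f3, `[[`, integer(1L), "cardinality")[sig == "1|2|3"],
               3L)

  expect_error(enumerateFactors(g, 0L), "between")
  expect_error(enumerateFactors(g, 4L), "between")
})

test_that("factor counts match brute force on a complete digraph", {
  set.seed(8)
  M <- matrix(rnorm(16), 4)                           # dense: complete
  g <- interactionGraph(M)
  for (k in 1:4)
    expect_equal(length(enumerateFactors(g, k)),
                 bruteFactorCount(g@weights, k))
})

test_that("graph coefficients equal direct determinant expansion", {
  ## a_1 = trace, a_n = det on a diagonal matrix
  g <- interactionGraph(diag(c(2, -3, 5)))
  expect_equal(coefficientViaFactors(g, 1L), 4)
  expect_equal(coefficientViaFactors(g, 3L), -30)

  ## 100 random dense matrices, n <= 6, against the Vandermonde oracle
  set.seed(77)
  for (k in 1:100) {
    n <- sample(2:6, 1L)
    M <- matrix(rnorm(n * n), n)
    g <- interactionGraph(M)
    got <- charPolyViaGraph(g)@coeffs
    expect_equal(got, oracleCharCoeffs(M), tolerance = 1e-9)
  }

  ## both autocatalytic families at random parameter draws
  set.seed(78)
  for (k in 1:20) {
    n <- sample(c(3L, 5L), 1L)
    net <- autocatalyticNetwork(n, runif(1, 0.2, 5), runif(1, 0.02, 1),
                                runif(1, 0.02, 1))
    A <- squaredJacobian(net)
    expect_equal(charPolyViaGraph(interactionGraph(A))@coeffs,
                 oracleCharCoeffs(A), tolerance = 1e-9)
  }
})

test_that("the graph route reproduces rPolynomial and handles edge cases", {
  set.seed(55)
  for (k in 1:5) {
    net <- autocatalyticNetwork(3, runif(1, 0.5, 3), runif(1, 0.05, 1),
                                runif(1, 0.05, 1))
    expect_equal(charPolyViaGraph(interactionGraph(squaredJacobian(net)))@coeffs,
                 rPolynomial(net)@coeffs, tolerance = 1e-10)
  }
  ## empty graph -> x^n
  expect_equal(charPolyViaGraph(interactionGraph(matrix(0, 4, 4)))@coeffs,
               c(1, 0, 0, 0, 0))
  ## deleting a vertex: subgraph coefficients match the principal submatrix
  M <- matrix(rnorm(25), 5)
  sub <- M[-2, -2]
  expect_equal(charPolyViaGraph(interactionGraph(sub))@coeffs,
               oracleCharCoeffs(sub), tolerance = 1e-9)
})

test_that("graph exports carry the weights", {
  g <- n3graph()
  dot <- graphAsDot(g)
  expect_true(any(grepl("digraph", dot)))
  expect_equal(sum(grepl("->", dot)), 9L)
  rep <- graphReport(g)
  expect_length(rep$cycles, 8L)
  expect_length(rep$factors[["2"]], 6L)
})
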