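# The reference complex for most examples is the labelled 1-simplex on
# vertices 1 and 2, whose group has the eight elements:
# {}, {{1}}, {{2}}, {{1,2}}, {{1},{2}}, {{1},{1,2}}, {{2},{1,2}}, K itself.

edge_elements <- function(K) {
  lapply(nonempty_subsets_chr(screp:::srep_skeys(K)), function(keys) {
    g_element(K, lapply(strsplit(keys, "|", fixed = TRUE), identity))
  })
}

test_that("symmetric difference is the group operation with identity and self-inverse", {
  K <- fixture("unit_edge")
  a <- g_element(K, list(1, c(1, 2)))
  e <- g_element(K)
  expect_length(g_product(a, a)$simplices, 0L)
  expect_identical(g_product(a, e)$simplices, a$simplices)
  ab <- g_product(g_element(K, list(1)), g_element(K, list(2)))
  expect_identical(ab$simplices, c("{1}", "{2}"))
  L <- fixture("triangle")
  expect_error(g_product(a, g_element(L, list(1))), class = "screp_error")
  expect_error(g_element(K, list(3)), class = "screp_error")
})

test_that("g_order is 1 for the identity and 2 otherwise", {
  K <- fixture("unit_edge")
  expect_identical(g_order(g_element(K)), 1L)
  expect_identical(g_order(g_element(K, list(1))), 2L)
  expect_identical(g_order(g_element(K, list(1, c(1, 2)))), 2L)
})

test_that("elements classify as simplex, subcomplex or simplex-set", {
  K <- fixture("unit_edge")
  cl <- classify_element(g_element(K, list(c(1, 2))))
  expect_identical(as.character(cl), "simplex")
  expect_false(attr(cl, "also_subcomplex"))

  cl_v <- classify_element(g_element(K, list(1)))
  expect_identical(as.character(cl_v), "simplex")
  expect_true(attr(cl_v, "also_subcomplex"))  # a lone vertex is both

  expect_identical(as.character(classify_element(g_element(K, list(1, c(1, 2))))),
                   "simplex-set")
  expect_identical(as.character(classify_element(g_element(K, list(1, 2, c(1, 2))))),
                   "subcomplex")
  expect_identical(as.character(classify_element(g_element(K, list(1, 2)))),
                   "subcomplex")
  expect_error(classify_element(g_element(K)), class = "screp_error")
})

test_that("minimal generators are the simplex singletons and span the group", {
  K <- fixture("unit_edge")
  gens <- minimal_generators(K)
  expect_length(gens, 3L)
  expect_setequal(vapply(gens, function(g) g$simplices, character(1)),
                  c("{1}", "{2}", "{1}|{2}"))

  # GF(2) span: every one of the 2^3 group elements is a product of a
  # unique generator subset
  spanned <- list(g_element(K))
  for (sub in nonempty_subsets_chr(as.character(1:3))) {
    x <- Reduce(g_product, gens[as.integer(sub)])
    spanned[[length(spanned) + 1L]] <- x
  }
  keys <- vapply(spanned, function(x) paste(x$simplices, collapse = ";"), character(1))
  expect_length(unique(keys), 8L)
  want <- vapply(c(list(g_element(K)), edge_elements(K)),
                 function(x) paste(x$simplices, collapse = ";"), character(1))
  expect_setequal(keys, want)

  expect_error(minimal_generators(close_under_faces(list())), class = "screp_error")
})

test_that("generator count equals |K| on random complexes", {
  set.seed(601)
  for (i in 1:10) {
    K <- rand_srep(sample(2:6, 1), runif(1, 0.3, 0.9), clique = runif(1) < 0.5)
    expect_length(minimal_generators(K), length(K$simplices))
  }
})

test_that("rho maps vertex sets of the group to the spanned simplex", {
  K <- fixture("unit_edge")
  expect_identical(rho(K, list(1, 2)), c("{1}", "{2}"))
  expect_identical(rho(K, list(1)), "{1}")
  expect_identical(rho(K, list(g_element(K, list(1)), g_element(K, list(2)))),
                   c("{1}", "{2}"))
  P <- fixture("path_n")
  expect_error(rho(P, list(1, 3)), class = "screp_error")
  expect_error(rho(K, list(g_element(K, list(c(1, 2))))), class = "screp_error")
})

test_that("g_distance counts the labelled symmetric difference", {
  K <- fixture("unit_edge")
  expect_identical(g_distance(K, K), 0L)
  L <- close_under_faces(list(1))
  expect_identical(g_distance(K, L), 2L)
  expect_identical(g_distance(close_under_faces(list(1)), close_under_faces(list(2))), 2L)
})

test_that("group and metric axioms hold on random instances", {
  set.seed(602)
  K <- rand_srep(6, 0.6, clique = TRUE)
  skeys <- screp:::srep_skeys(K)
  pick <- function() {
    n <- sample(0:length(skeys), 1)
    structure(list(simplices = sort(sample(skeys, n), method = "radix")),
              ref = screp:::srep_ref(K), complex = K, class = "g_element")
  }
  for (i in 1:200) {
    a <- pick(); b <- pick(); cc <- pick()
    lhs <- g_product(g_product(a, b), cc)
    rhs <- g_product(a, g_product(b, cc))
    expect_identical(lhs$simplices, rhs$simplices)
    expect_lte(g_order(g_product(a, a)), 1L)
  }
  for (i in 1:60) {
    A <- rand_srep(sample(2:5, 1), runif(1))
    B <- rand_srep(sample(2:5, 1), runif(1))
    C <- rand_srep(sample(2:5, 1), runif(1))
    expect_gte(g_distance(A, B), 0L)
    expect_identical(g_distance(A, A), 0L)
    expect_identical(g_distance(A, B), g_distance(B, A))
    expect_lte(g_distance(A, C), g_distance(A, B) + g_distance(B, C))
  }
})

test_that("phi_identify is the canonical projection and matches the simplicial operation", {
  E <- fixture("unit_edge")
  phi <- phi_identify(E, 1, 2, kind = "adjacent")
  expect_length(phi(g_element(E, list(2, c(1, 2))))$simplices, 0L)
  expect_length(phi(g_element(E))$simplices, 0L)
  expect_identical(phi(g_element(E, list(1)))$simplices, "{1}")
  expect_error(phi_identify(fixture("path_n"), 1, 2, kind = "adjacent"),
               class = "screp_error")
  expect_error(phi_identify(E, 1, 2, kind = "nonadjacent"), class = "screp_error")

  set.seed(603)
  checked <- 0L
  for (i in 1:20) {
    K <- rand_srep(sample(3:6, 1), runif(1, 0.3, 0.9), clique = runif(1) < 0.5)
    prs <- exchangeable_pairs(K)
    if (length(prs) == 0L) next
    p <- prs[[1]]
    chk <- screp:::check_identification(K, p[1], p[2])
    phi <- phi_identify(K, p[1], p[2], kind = chk$kind)
    # homomorphism on random pairs
    skeys <- screp:::srep_skeys(K)
    for (j in 1:5) {
      a <- g_element(K, lapply(sample(skeys, sample(0:3, 1)), function(k)
        strsplit(k, "|", fixed = TRUE)[[1]]))
      b <- g_element(K, lapply(sample(skeys, sample(0:3, 1)), function(k)
        strsplit(k, "|", fixed = TRUE)[[1]]))
      expect_identical(phi(g_product(a, b))$simplices,
                       g_product(phi(a), phi(b))$simplices)
    }
    # the surviving simplex family matches the identification output
    op <- if (chk$kind == "adjacent") adjacent_vertex_identification
    else nonadjacent_vertex_identification
    expect_true(oracle_isomorphic(attr(phi, "codomain"), op(K, p[1], p[2])))
    checked <- checked + 1L
  }
  expect_gt(checked, 3L)
})

test_that("phi_substitute is an isomorphism of G-representations", {
  E <- fixture("unit_edge")
  fwd <- phi_substitute(E, 1, 7)
  back <- phi_substitute(attr(fwd, "codomain"), 7, 1)
  full <- g_element(E, list(1, 2, c(1, 2)))
  expect_identical(back(fwd(full))$simplices, full$simplices)
  expect_identical(fwd(full)$simplices, c("{2}", "{2}|{7}", "{7}"))
  gens_img <- lapply(minimal_generators(E), fwd)
  expect_setequal(vapply(gens_img, function(g) g$simplices, character(1)),
                  vapply(minimal_generators(attr(fwd, "codomain")),
                         function(g) g$simplices, character(1)))
})
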