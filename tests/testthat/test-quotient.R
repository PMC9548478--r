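test_that("vertex_orbits partitions Vert(K) into group orbits", {
  K <- fixture("triangle")
  expect_identical(vertex_orbits(K, list(c(1, 2))),
                   list(c("{1}", "{2}"), "{3}"))
  expect_identical(vertex_orbits(K, list(c(1, 2, 3))),
                   list(c("{1}", "{2}", "{3}")))
  expect_identical(vertex_orbits(K, list()), list("{1}", "{2}", "{3}"))
  P <- fixture("path_n")
  expect_error(vertex_orbits(P, list(c(1, 2))), class = "screp_error")
})

test_that("orbit_space reproduces the worked quotients of the filled triangle", {
  K <- fixture("triangle")

  q <- orbit_space(K, list(c(1, 2)))
  expect_identical(complex_dimension(q$complex), 1L)
  expect_setequal(names(q$complex$vertices), c("{3}", "{{1},{2}}"))
  expect_identical(unname(q$vertex_map[c("{1}", "{2}", "{3}")]),
                   c("{{1},{2}}", "{{1},{2}}", "{3}"))

  h <- orbit_space(K, list(c(1, 2, 3)))
  expect_identical(complex_dimension(h$complex), 0L)
  expect_identical(names(h$complex$vertices), "{{1},{2},{3}}")

  triv <- orbit_space(K, list())
  expect_true(screp:::srep_equal(triv$complex, K))
})

test_that("quotients validate, projections are surjective simplicial, labels union", {
  set.seed(301)
  for (i in 1:40) {
    K <- rand_srep(sample(3:8, 1), runif(1, 0.3, 0.9), clique = runif(1) < 0.5)
    prs <- exchangeable_pairs(K)
    act <- if (length(prs) > 0L) sample(prs, sample(seq_along(prs), 1)) else list()
    q <- orbit_space(K, act)
    expect_true(validate_srep(q$complex)$ok)
    # surjective on vertices and simplices
    expect_setequal(unique(unname(q$vertex_map)), names(q$complex$vertices))
    img <- unique(vapply(K$simplices, function(s) {
      paste(sort(unique(unname(q$vertex_map[s])), method = "radix"), collapse = "|")
    }, character(1)))
    expect_setequal(img, screp:::srep_skeys(q$complex))
    # orbit labels are unions of member labels
    for (b in vertex_orbits(K, act)) {
      ok <- unname(q$vertex_map[[b[1]]])
      expect_identical(vertex_label(q$complex, ok),
                       sort(unique(unlist(lapply(b, vertex_label, K = K)))))
    }
  }
})

test_that("same-orbit vertices are exchangeable and representatives are interchangeable", {
  set.seed(302)
  for (i in 1:25) {
    K <- rand_srep(sample(3:7, 1), runif(1, 0.3, 0.9), clique = TRUE)
    prs <- exchangeable_pairs(K)
    if (length(prs) == 0L) next
    act <- sample(prs, sample(seq_along(prs), 1))
    blocks <- vertex_orbits(K, act)
    for (b in blocks) {
      if (length(b) >= 2L) {
        cmb <- utils::combn(b, 2L, simplify = FALSE)
        for (p in cmb) expect_true(are_exchangeable(K, p[1], p[2]))
      }
    }
    # simplex-representative independence: every system of representatives
    # of a quotient simplex spans a simplex of K
    q <- orbit_space(K, act)
    names(blocks) <- vapply(blocks, function(b) unname(q$vertex_map[[b[1]]]), character(1))
    for (s in q$complex$simplices) {
      reps <- expand.grid(lapply(s, function(ov) blocks[[ov]]),
                          stringsAsFactors = FALSE)
      for (r in seq_len(nrow(reps))) {
        key <- paste(sort(unique(unname(unlist(reps[r, ]))), method = "radix"),
                     collapse = "|")
        expect_true(key %in% screp:::srep_skeys(K))
      }
    }
  }
})

test_that("fundamental domains are isomorphic to the orbit space for any rule", {
  K <- fixture("triangle")
  fd_min <- fundamental_domain(K, list(c(1, 2)), "min")
  expect_setequal(names(fd_min$vertices), c("{1}", "{3}"))
  fd_max <- fundamental_domain(K, list(c(1, 2)), "max")
  expect_setequal(names(fd_max$vertices), c("{2}", "{3}"))
  expect_true(oracle_isomorphic(fd_min, fd_max))
  expect_true(screp:::srep_equal(fundamental_domain(K, list()), K))

  set.seed(303)
  for (i in 1:25) {
    Kr <- rand_srep(sample(3:8, 1), runif(1, 0.3, 0.9), clique = runif(1) < 0.5)
    prs <- exchangeable_pairs(Kr)
    if (length(prs) == 0L) next
    act <- sample(prs, sample(seq_along(prs), 1))
    q <- orbit_space(Kr, act)
    for (rule in list("min", "max", function(b) sample(b, 1))) {
      expect_true(oracle_isomorphic(q$complex, fundamental_domain(Kr, act, rule)))
    }
  }
})

test_that("project_transposition projects or degenerates per orbit membership", {
  S <- fixture("square_cycle")
  pr <- project_transposition(S, list(c(1, 3)), c(2, 4))
  expect_false(pr$identity)
  expect_identical(pr$pair, c("{2}", "{4}"))
  expect_true(are_exchangeable(pr$complex, pr$pair[1], pr$pair[2]))

  K <- fixture("triangle")
  expect_true(project_transposition(K, list(c(1, 2)), c(1, 2))$identity)
  pr2 <- project_transposition(K, list(c(1, 2)), c(1, 3))
  expect_identical(pr2$pair, c("{3}", "{{1},{2}}"))
  expect_true(are_exchangeable(pr2$complex, pr2$pair[1], pr2$pair[2]))
  expect_error(project_transposition(fixture("path_n"), list(), c(1, 2)),
               class = "screp_error")
})

test_that("final_orbit_space reaches a fixpoint with the expected traces", {
  tr <- final_orbit_space(fixture("triangle"))
  expect_length(tr$stages, 1L)
  expect_identical(names(tr$final$vertices), "{{1},{2},{3}}")

  tr2 <- final_orbit_space(fixture("square_cycle"))
  expect_length(tr2$stages, 2L)
  expect_identical(complex_dimension(tr2$stages[[1]]$complex), 1L)
  expect_identical(complex_dimension(tr2$final), 0L)

  # the 4-path is exchange-rigid: its only nontrivial symmetry (the
  # reversal) moves more than two vertices
  P <- fixture("path_n", n = 4)
  expect_length(exchangeable_pairs(P), 0L)
  tr3 <- final_orbit_space(P)
  expect_length(tr3$stages, 0L)
  expect_true(screp:::srep_equal(tr3$final, P))
})

test_that("batched reductions are confluent with the simultaneous reduction", {
  set.seed(304)
  done <- 0L
  for (i in 1:40) {
    K <- rand_srep(sample(4:8, 1), runif(1, 0.3, 0.9), clique = runif(1) < 0.5)
    prs <- exchangeable_pairs(K)
    if (length(prs) < 2L) next
    batch <- sample(prs, sample(seq_len(length(prs) - 1L), 1))
    K1 <- screp:::quotient_by_pairs(K, batch)$complex
    fin_batched <- final_orbit_space(K1)$final
    fin_direct <- final_orbit_space(K)$final
    expect_true(oracle_isomorphic(fin_batched, fin_direct))
    done <- done + 1L
  }
  expect_gt(done, 5L)
})

test_that("vertex count drops by the number of nontrivial merges", {
  set.seed(305)
  for (i in 1:25) {
    K <- rand_srep(sample(3:8, 1), runif(1, 0.3, 0.9), clique = TRUE)
    prs <- exchangeable_pairs(K)
    if (length(prs) == 0L) next
    act <- sample(prs, sample(seq_along(prs), 1))
    blocks <- vertex_orbits(K, act)
    merges <- sum(lengths(blocks) - 1L)
    q <- orbit_space(K, act)
    expect_identical(length(q$complex$vertices), length(K$vertices) - merges)
  }
})
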