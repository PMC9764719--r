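test_that("d-separation handles canonical chain and collider structures", {
  chain <- dag_create(c("A -> B", "B -> C"))
  expect_true(d_separated(chain, "A", "C", "B"))
  expect_false(d_separated(chain, "A", "C"))

  collider <- dag_create(c("A -> B", "C -> B"))
  expect_true(d_separated(collider, "A", "C"))
  expect_false(d_separated(collider, "A", "C", "B"))

  # conditioning on a collider's descendant also opens the path
  desc <- dag_create(c("A -> B", "C -> B", "B -> D"))
  expect_false(d_separated(desc, "A", "C", "D"))

  expect_error(d_separated(chain, "A", "Z"), class = "occmsm_validation_error")
  expect_error(d_separated(chain, "A", "B", "A"),
               class = "occmsm_validation_error")
})

test_that("conditioning on the day-two turnover collider opens the staffing path", {
  g <- occupancy_dag()
  # CU1 -> PT2 <- U -> M2 is opened by conditioning on PT2
  expect_false(d_separated(g, "CU1", "M2", c("PT2", "CU2", "C", "PT1")))
  # without PT2 in the conditioning set the path through it stays blocked,
  # but the direct causal path CU1 -> CU2 -> M2 must then be blocked by CU2
  expect_false(d_separated(g, "CU1", "M2", c("C", "PT1")))
})

test_that("backdoor criterion accepts confounders and rejects mediators", {
  tri <- dag_create(c("L -> A", "L -> Y", "A -> Y"))
  expect_true(backdoor_valid(tri, "A", "Y", "L"))
  expect_false(backdoor_valid(tri, "A", "Y", character()))

  med <- dag_create(c("A -> M", "M -> Y"))
  expect_false(backdoor_valid(med, "A", "Y", "M"))

  latent <- dag_create(c("U -> A", "U -> Y", "A -> Y"), latent = "U")
  expect_error(backdoor_valid(latent, "A", "Y", "U"),
               class = "occmsm_validation_error")
})

test_that("no measured adjustment set is backdoor-valid for the occupancy DAG", {
  g <- occupancy_dag()
  measured <- c("C", "PT1", "PCCL1", "PT2", "PCCL2", "M1")
  found <- character(0)
  for (k in 0:length(measured)) {
    zsets <- if (k == 0) list(character(0)) else
      asplit(utils::combn(measured, k), 2L)
    for (z in zsets) {
      if (backdoor_valid(g, c("CU1", "CU2"), "M2", as.character(z)))
        found <- c(found, paste(z, collapse = ","))
    }
  }
  expect_length(found, 0)
})

test_that("treatment-confounder feedback is detected with witness paths", {
  g <- occupancy_dag()
  res <- detect_tcf(g)
  expect_true(res$tcf)
  conf <- vapply(res$witnesses, `[[`, "", "confounder")
  expect_true("PT2" %in% conf)
  w <- res$witnesses[[which(conf == "PT2")[1]]]
  expect_identical(w$from_exposure, c("CU1", "PT2"))
  expect_identical(w$outcome_link, c("PT2", "U", "M2"))

  # removing the feedback arrow removes TCF through turnover
  keep <- !(g$edges$from == "CU1" & g$edges$to == "PT2")
  g2 <- dag_create(g$edges[keep, ], latent = "U", roles = g$roles)
  expect_false(detect_tcf(g2)$tcf)

  # a single-time-point graph has no feedback by construction
  base <- dag_create(c("L -> A", "L -> Y", "A -> Y", "C -> A", "C -> Y"),
                     roles = data.frame(node = c("A", "L", "Y", "C"),
                                        role = c("exposure", "confounder",
                                                 "outcome", "baseline"),
                                        time = c(1L, 1L, 1L, NA)))
  expect_false(detect_tcf(base)$tcf)

  no_roles <- dag_create(c("A -> B"))
  expect_error(detect_tcf(no_roles), class = "occmsm_config_error")
})

test_that("the text format round-trips a DAG with roles and latents", {
  g <- occupancy_dag()
  path <- tempfile(fileext = ".dag")
  dag_write(g, path)
  g2 <- dag_read(path)
  expect_setequal(g2$nodes, g$nodes)
  expect_identical(
    sort(paste(g2$edges$from, g2$edges$to)),
    sort(paste(g$edges$from, g$edges$to)))
  expect_identical(g2$nodes[g2$latent], "U")
  expect_true(detect_tcf(g2)$tcf)
})

test_that("cyclic and malformed graphs are rejected", {
  expect_error(dag_create(c("A -> B", "B -> A")),
               class = "occmsm_validation_error")
  expect_error(dag_create(c("A -> B", "B -> C", "C -> A")),
               class = "occmsm_validation_error")
  expect_error(dag_create("A - B"), class = "occmsm_validation_error")
  expect_error(dag_create(c("A -> A")), class = "occmsm_validation_error")
})

test_that("d-separation is symmetric and satisfies the local Markov property", {
  set.seed(42)
  for (i in 1:40) {
    g <- random_dag(6, p_edge = 0.4)
    q <- dsep_queries(g$nodes, max_z = 2)[[sample.int(50, 1)]]
    expect_identical(d_separated(g, q$x, q$y, q$z),
                     d_separated(g, q$y, q$x, q$z))
  }
  g <- occupancy_dag()
  for (v in g$nodes) {
    nd <- setdiff(g$nodes, c(v, dag_descendants(g, v), g$parents[[v]]))
    if (length(nd))
      expect_true(d_separated(g, v, nd, g$parents[[v]]))
  }
})

test_that("reachability d-separation agrees with the path-enumeration oracle", {
  # exhaustive over all acyclic orientations on three nodes, all queries
  for (g in enumerate_dags(c("A", "B", "C"))) {
    for (q in dsep_queries(g$nodes)) {
      expect_identical(d_separated(g, q$x, q$y, q$z),
                       oracle_d_separated(g, q$x, q$y, q$z),
                       info = paste(paste(g$edges$from, "->", g$edges$to,
                                          collapse = "; "),
                                    "|", q$x, q$y, paste(q$z, collapse = ",")))
    }
  }
  # random graphs at five and eight nodes with random queries
  set.seed(7)
  for (n in c(5, 8)) {
    for (i in 1:60) {
      g <- random_dag(n, p_edge = 0.35)
      qs <- dsep_queries(g$nodes, max_z = 3)
      for (q in sample(qs, 5)) {
        expect_identical(d_separated(g, q$x, q$y, q$z),
                         oracle_d_separated(g, q$x, q$y, q$z))
      }
    }
  }
})
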