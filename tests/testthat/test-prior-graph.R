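fig1_degradation <- c(
  "RLS2->dp39", "RLS2->dp12", "RLS2->dp37",
  "dp39->dp7", "dp39->dp15", "dp39->dp17",
  "RSS174->dp44", "RSS175->dp44"
)

test_that("the fixture records reproduce the hypothesized pathway exactly", {
  for (s in c(1, 7, 123)) {
    g <- build_prior_graph(fragment_fixture(s), rubisco_regulation())
    expect_setequal(edge_set(g, "degradation"), fig1_degradation)
    expect_setequal(edge_set(g, "regulation"),
                    c("RSS174->RLS2", "RSS175->RLS2", "RLS2->RLS2"))
  }
})

test_that("fragment masses are below their parents and the subgraph is a DAG", {
  recs <- fragment_fixture(2)
  g <- build_prior_graph(recs)
  mass <- stats::setNames(recs$mass_kda, recs$id)
  deg <- g$edges[g$edges$kind == "degradation", ]
  expect_true(all(mass[deg$source] > mass[deg$target]))
  ig <- as_igraph(g, "degradation")
  expect_true(igraph::is_dag(ig))
})

test_that("records with no fragments give a graph with nodes only", {
  recs <- protein_records(c("A", "B"), c("intact", "intact"), c(50, 40),
                          c("A", "B"), list("P1", "P2"))
  g <- build_prior_graph(recs)
  expect_equal(nrow(g$nodes), 2)
  expect_equal(nrow(g$edges), 0)
})

test_that("graph construction is order-independent", {
  recs <- fragment_fixture(5)
  g1 <- build_prior_graph(recs, rubisco_regulation())
  set.seed(1)
  g2 <- build_prior_graph(recs[sample(nrow(recs)), ], rubisco_regulation())
  expect_identical(g1$edges, g2$edges)
})

test_that("randomized planted containment matches the all-pairs oracle", {
  set.seed(2024)
  for (rep in 1:10) {
    n <- 8
    # random nested interval structures on one reference
    ivs <- list(matrix(c(0, 500), 1))
    for (i in 2:n) {
      parent <- ivs[[sample(i - 1, 1)]]
      lo <- parent[1, 1]
      hi <- parent[1, 2]
      if (hi - lo < 20) {
        ivs[[i]] <- matrix(c(lo, hi), 1)
      } else {
        a <- sample(lo:(hi - 10), 1)
        b <- sample((a + 5):hi, 1)
        ivs[[i]] <- matrix(c(a, b), 1)
      }
    }
    width <- vapply(ivs, function(m) m[1, 2] - m[1, 1], numeric(1))
    # mass decreasing with width, jittered but order-preserving
    mass <- 5 + width / 10 + stats::runif(n, 0, 0.3)
    ids <- paste0("s", seq_len(n))
    tier <- c("intact", rep("fragment", n - 1))
    ref <- rep("s1", n)
    recs <- protein_records(ids, tier, mass, ref, ivs)
    recs$reference_subunit[1] <- "s1"
    g <- build_prior_graph(recs)
    oracle <- oracle_degradation_edges(recs)
    expect_setequal(edge_set(g, "degradation"),
                    paste(oracle$source, oracle$target, sep = "->"))
  }
})

test_that("mutual containment with equal mass is a named cycle error", {
  recs <- protein_records(
    c("a", "b"), c("fragment", "fragment"), c(10, 10), c("R", "R"),
    list(matrix(c(5, 50), 1), matrix(c(5, 50), 1))
  )
  expect_error(build_prior_graph(recs), "cyclic degradation evidence")
})

test_that("regulation edges pass through verbatim, unknown endpoints error", {
  recs <- fragment_fixture(1)
  expect_error(
    build_prior_graph(recs, data.frame(source = "nope", target = "RLS2")),
    "unknown proteins")
})

test_that("to_sem_skeleton gives one free path per edge, one variance per node", {
  g <- build_prior_graph(fragment_fixture(1), rubisco_regulation())
  sk <- to_sem_skeleton(g)
  expect_equal(length(sk$observed), 10)
  expect_equal(sum(sk$params$class == "path"), nrow(g$edges))
  expect_equal(sum(sk$params$class == "variance"), 10)
  # empty graph
  empty <- build_prior_graph(protein_records("A", "intact", 1, "A",
                                             list("P")))
  sk0 <- to_sem_skeleton(empty)
  expect_equal(n_free_params(sk0), 1) # just the variance of A
})

test_that("random DAG skeletons carry one structural parameter per edge", {
  set.seed(99)
  for (rep in 1:5) {
    p <- sample(4:8, 1)
    vars <- paste0("v", seq_len(p))
    pairs <- t(utils::combn(vars, 2))
    take <- sample(nrow(pairs), sample(2:min(6, nrow(pairs)), 1))
    m <- sem_model(paths = data.frame(from = pairs[take, 1],
                                      to = pairs[take, 2]),
                   observed = vars)
    expect_equal(sum(m$params$class == "path"), length(take))
  }
})

test_that("graph export writes readable GraphML, DOT and JSON", {
  g <- build_prior_graph(fragment_fixture(1), rubisco_regulation())
  dir <- withr::local_tempdir()
  write_pathway_graph(g,
                      graphml = file.path(dir, "g.graphml"),
                      dot = file.path(dir, "g.dot"),
                      json = file.path(dir, "g.json"))
  back <- igraph::read_graph(file.path(dir, "g.graphml"), format = "graphml")
  expect_equal(igraph::vcount(back), 10)
  expect_equal(igraph::ecount(back), nrow(g$edges))
  expect_setequal(unique(igraph::edge_attr(back, "kind")),
                  c("degradation", "regulation"))
  js <- jsonlite::read_json(file.path(dir, "g.json"), simplifyVector = TRUE)
  expect_equal(nrow(js$edges), nrow(g$edges))
  expect_true(any(grepl("->", readLines(file.path(dir, "g.dot")))))
})
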