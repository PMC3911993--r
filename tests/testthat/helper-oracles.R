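# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (per-residue scans, double loops, all-pairs checks)
# so they share no code with the implementation they check.

# covariance by explicit double loop, divisor N-1
oracle_cov <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  S <- matrix(0, p, p, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      xi <- X[, i] - mean(X[, i])
      xj <- X[, j] - mean(X[, j])
      S[i, j] <- sum(xi * xj) / (n - 1)
    }
  }
  S
}

# residue-by-residue interval coverage on integer positions
oracle_covered <- function(inner, outer) {
  inner <- matrix(inner, ncol = 2)
  outer <- matrix(outer, ncol = 2)
  if (nrow(inner) == 0) return(FALSE)
  inner_res <- unlist(lapply(seq_len(nrow(inner)), function(k) {
    seq(inner[k, 1], inner[k, 2] - 1)
  }))
  outer_res <- unlist(lapply(seq_len(nrow(outer)), function(k) {
    seq(outer[k, 1], outer[k, 2] - 1)
  }))
  all(inner_res %in% outer_res)
}

# all-pairs containment scan + brute-force transitive reduction:
# drop an edge when a longer degradation path connects the same pair
oracle_degradation_edges <- function(records) {
  n <- nrow(records)
  edges <- data.frame(source = character(), target = character())
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      a <- records[i, ]
      b <- records[j, ]
      if (b$tier != "fragment") next
      if (is.numeric(a$evidence[[1]]) != is.numeric(b$evidence[[1]])) next
      if (a$mass_kda <= b$mass_kda) next
      if (sequence_contained(b, a)) {
        edges <- rbind(edges, data.frame(source = a$id, target = b$id))
      }
    }
  }
  # path of length >= 2 from s to t using all scanned edges?
  has_long_path <- function(s, t) {
    mids <- edges$target[edges$source == s]
    frontier <- setdiff(mids, t)
    seen <- character()
    while (length(frontier)) {
      v <- frontier[1]
      frontier <- frontier[-1]
      if (v %in% seen) next
      seen <- c(seen, v)
      nxt <- edges$target[edges$source == v]
      if (t %in% nxt) return(TRUE)
      frontier <- c(frontier, nxt)
    }
    FALSE
  }
  keep <- !mapply(has_long_path, edges$source, edges$target)
  edges <- edges[keep, , drop = FALSE]
  edges[order(edges$source, edges$target), , drop = FALSE]
}

# correlation grouping by explicit O(p^2) scan + union-find
oracle_collinear_groups <- function(X, threshold) {
  X <- as.matrix(X)
  p <- ncol(X)
  parent <- seq_len(p)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      if (abs(stats::cor(X[, i], X[, j])) > threshold) {
        parent[find(j)] <- find(i)
      }
    }
  }
  roots <- vapply(seq_len(p), find, integer(1))
  groups <- split(colnames(X), roots)
  groups <- unname(groups[lengths(groups) > 1])
  lapply(groups, sort)
}

# OLS closed form for y ~ X (no intercept needed: centered data)
oracle_ols <- function(X, y) {
  X <- as.matrix(X)
  X <- scale(X, center = TRUE, scale = FALSE)
  y <- y - mean(y)
  drop(solve(crossprod(X), crossprod(X, y)))
}

# small helper models -------------------------------------------------------

single_path_model <- function() {
  sem_model(paths = data.frame(from = "x", to = "y"))
}

single_path_truth <- function(b = 0.5, psi_x = 1, psi_y = 1) {
  sem_true_model(single_path_model(),
                 c("y~x" = b, "x~~x" = psi_x, "y~~y" = psi_y))
}

# a saturated model on p observed variables (all pairwise covariances free)
saturated_model <- function(vars) {
  combs <- utils::combn(vars, 2)
  sem_model(observed = vars,
            covariances = data.frame(a = combs[1, ], b = combs[2, ]))
}

edge_set <- function(graph, kind = NULL) {
  e <- graph$edges
  if (!is.null(kind)) e <- e[e$kind == kind, ]
  sort(paste(e$source, e$target, sep = "->"))
}
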