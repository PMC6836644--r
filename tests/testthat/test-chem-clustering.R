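test_that("tanimoto similarity counts bits correctly", {
  expect_equal(tanimoto_similarity(c(1, 0, 1), c(1, 0, 1)), 1)
  expect_equal(tanimoto_similarity(c(1, 1, 0, 0), c(0, 0, 1, 1)), 0)
  expect_equal(tanimoto_similarity(c(1, 1, 0, 0), c(1, 0, 0, 0)), 0.5)
  expect_equal(tanimoto_similarity(c(0, 0), c(0, 0)), 1)  # both-empty rule
  expect_equal(tanimoto_distance(c(1, 1, 0, 0), c(1, 0, 0, 0)), 0.5)
  expect_error(tanimoto_similarity(c(1, 0), c(1, 0, 0)), "length")
})

test_that("tanimoto matches brute-force bit counting on random pairs", {
  set.seed(17)
  for (i in 1:100) {
    n <- sample(4:64, 1)
    a <- rbinom(n, 1, 0.4); b <- rbinom(n, 1, 0.4)
    inter <- 0; union <- 0
    for (j in 1:n) {
      if (a[j] == 1 && b[j] == 1) inter <- inter + 1
      if (a[j] == 1 || b[j] == 1) union <- union + 1
    }
    brute <- if (union == 0) 1 else inter / union
    expect_equal(tanimoto_similarity(a, b), brute)
  }
})

test_that("tanimoto distance satisfies the triangle inequality", {
  set.seed(23)
  for (i in 1:200) {
    n <- sample(6:40, 1)
    a <- rbinom(n, 1, 0.5); b <- rbinom(n, 1, 0.5); c <- rbinom(n, 1, 0.5)
    expect_lte(tanimoto_distance(a, c),
               tanimoto_distance(a, b) + tanimoto_distance(b, c) + 1e-12)
  }
})

test_that("leader clustering walks the hand-computed 4-point example", {
  # d(1,2) = 0.2, d(3,4) = 0.1, all cross distances 1 > 0.35
  fps <- rbind(
    p1 = c(rep(1, 5), rep(0, 15)),
    p2 = c(rep(1, 4), rep(0, 16)),
    p3 = c(rep(0, 10), rep(1, 9), 0),
    p4 = c(rep(0, 10), rep(1, 10))
  )
  expect_equal(tanimoto_distance(fps["p1", ], fps["p2", ]), 0.2)
  expect_equal(tanimoto_distance(fps["p3", ], fps["p4", ]), 0.1)
  expect_equal(tanimoto_distance(fps["p1", ], fps["p3", ]), 1)

  cl <- leader_cluster(fps, 0.35, ordering = c("p1", "p2", "p3", "p4"))
  expect_length(cl, 2)
  expect_equal(cl[[1]]$center, "p1")
  expect_setequal(cl[[1]]$members, c("p1", "p2"))
  expect_equal(cl[[2]]$center, "p3")
  expect_setequal(cl[[2]]$members, c("p3", "p4"))

  # identical fingerprints collapse into one cluster
  same <- matrix(rep(c(1, 0, 1, 1), each = 5), 5, 4,
                 dimnames = list(paste0("s", 1:5), NULL))
  expect_length(leader_cluster(same, 0.35), 1)

  # zero threshold with distinct fingerprints: all singletons
  singles <- leader_cluster(fps, 0)
  expect_length(singles, 4)

  expect_error(leader_cluster(fps, 0.35, ordering = c("p1", "p2", "p3", "px")),
               "unknown id")
  expect_error(leader_cluster(fps, 1.5), "\\[0, 1\\]")
})

test_that("leader clustering invariants hold on random fingerprints", {
  set.seed(31)
  for (i in 1:10) {
    n <- 40
    fps <- matrix(rbinom(n * 24, 1, 0.3), n, 24,
                  dimnames = list(sprintf("m%02d", 1:n), NULL))
    thr <- sample(c(0.2, 0.35, 0.5), 1)
    cl <- leader_cluster(fps, thr)
    all_members <- unlist(lapply(cl, `[[`, "members"))
    expect_setequal(all_members, rownames(fps))
    expect_equal(anyDuplicated(all_members), 0)
    for (c1 in cl) {
      for (m in c1$members) {
        expect_lte(tanimoto_distance(fps[c1$center, ], fps[m, ]), thr)
      }
    }
    centers <- vapply(cl, `[[`, "", "center")
    if (length(centers) > 1) {
      pairs <- utils::combn(centers, 2)
      for (j in seq_len(ncol(pairs))) {
        expect_gt(tanimoto_distance(fps[pairs[1, j], ], fps[pairs[2, j], ]),
                  thr)
      }
    }
    # determinism under identical ordering
    expect_identical(leader_cluster(fps, thr), cl)
  }
})

test_that("select_representatives keeps the top-theta member per cluster", {
  mk <- function(center, members) {
    structure(list(center = center, members = members, threshold = 0.35),
              class = "chem_cluster")
  }
  clusters <- list(mk("a", c("a", "b")), mk("c", "c"), mk("d", c("d", "e")))
  theta <- c(a = 0.9, b = 0.7, c = 0.5, d = 0.3, e = 0.3)
  expect_equal(select_representatives(clusters, theta), c("a", "c", "d"))
  # tie in the last cluster resolved to the lexicographically smaller id
  theta2 <- c(a = 0.1, b = 0.7, c = 0.5, e = 0.3, d = 0.3)
  expect_equal(select_representatives(clusters, theta2), c("b", "c", "d"))
  expect_error(select_representatives(clusters, theta[-2]),
               "no relevance score for compound b")
})

test_that("diversity_stats matches brute-force pair enumeration", {
  fps <- rbind(a = c(1, 1, 0, 0), b = c(1, 0, 0, 0), c = c(0, 0, 1, 1))
  st <- diversity_stats(fps, training = fps[1:2, , drop = FALSE])
  d_ab <- tanimoto_distance(fps[1, ], fps[2, ])
  d_ac <- tanimoto_distance(fps[1, ], fps[3, ])
  d_bc <- tanimoto_distance(fps[2, ], fps[3, ])
  expect_equal(st$pairwise_mean, mean(c(d_ab, d_ac, d_bc)))
  expect_equal(st$pairwise_sd, sd(c(d_ab, d_ac, d_bc)))
  # a and b sit in the training set; c's nearest is b or a
  expect_equal(st$nearest_mean, mean(c(0, 0, min(d_ac, d_bc))))

  ident <- rbind(x = c(1, 0, 1), y = c(1, 0, 1))
  st2 <- diversity_stats(ident)
  expect_equal(st2$pairwise_mean, 0)
  expect_equal(st2$pairwise_sd, 0)
  expect_true(is.na(st2$nearest_mean))

  expect_error(diversity_stats(fps[1, , drop = FALSE]), "at least 2")
  expect_error(diversity_stats(fps, training = matrix(0, 0, 4)), "empty")
})
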