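test_that("edge gradients are positive, complementary, and loser-seeking", {
  # tie of any size splits evenly
  g <- edge_gradient(c(0, 3, 7), c(0, 3, 7))
  expect_equal(g$toward_a, rep(0.5, 3))

  # 2:1 with epsilon 1 -> 3/5 toward the 1-point side
  g <- edge_gradient(2, 1, epsilon = 1)
  expect_equal(g$toward_b, 3 / 5)
  expect_equal(g$toward_a, 2 / 5)

  # random scores: weights strictly positive, sum to 1, larger one points
  # at whichever side scored fewer points
  set.seed(11)
  sa <- sample(0:20, 50, replace = TRUE)
  sb <- sample(0:20, 50, replace = TRUE)
  for (eps in c(0.5, 1, 2)) {
    g <- edge_gradient(sa, sb, epsilon = eps)
    expect_true(all(g$toward_a > 0 & g$toward_b > 0))
    expect_equal(g$toward_a + g$toward_b, rep(1, 50))
    dec <- sa != sb
    expect_true(all(((g$toward_a > g$toward_b) == (sb > sa))[dec]))
  }

  expect_error(edge_gradient(1, 0, epsilon = 0), "positive")
  expect_error(edge_gradient(1, 0, epsilon = -1), "positive")
})

test_that("transition matrix is column-stochastic with the games' support", {
  tr <- transition_matrix(build_network(tie_chain()))
  expect_equal(tr$T[, "B"], c(A = 0.5, B = 0, C = 0.5))
  expect_equal(tr$T["B", "A"], 1)
  expect_equal(tr$T["B", "C"], 1)

  for (seed in 1:5) {
    net <- build_network(random_games(7, n_extra = 12, seed = seed))
    for (dir in c("toward_loser", "toward_stronger")) {
      tr <- transition_matrix(net, direction = dir)
      expect_equal(colSums(tr$T), setNames(rep(1, 7), net$teams))
      expect_true(all(tr$T >= 0))
      off <- row(tr$T) != col(tr$T)
      expect_equal(unname((tr$T > 0)[off]), unname((net$games_played > 0)[off]))
    }
  }
})

test_that("transition entries on the transitive triangle match hand substitution", {
  # A beats B 2:0, B beats C 2:0, A beats C 2:0, eps = 1: every edge has
  # normalizer 2+0+2 = 4, gradient 3/4 toward the loser and 1/4 toward the
  # winner; every degree is 2, so dividing by k and renormalizing columns:
  expected <- matrix(
    c(0,   1 / 4, 1 / 2,
      1 / 2, 0,   1 / 2,
      1 / 2, 3 / 4, 0),
    nrow = 3, byrow = TRUE, dimnames = list(c("A", "B", "C"), c("A", "B", "C"))
  )
  tr <- transition_matrix(build_network(transitive_triangle()), epsilon = 1)
  expect_equal(tr$T, expected)
})

test_that("stationary solve matches balance equations and the eigen oracle", {
  v <- stationary_distribution(transition_matrix(build_network(tie_chain())))
  expect_equal(v, c(A = 0.25, B = 0.5, C = 0.25))

  for (seed in 1:10) {
    net <- build_network(random_games(8, n_extra = 15, seed = seed))
    tr <- transition_matrix(net)
    v <- stationary_distribution(tr)
    expect_true(all(v >= 0))
    expect_equal(sum(v), 1)
    expect_lt(max(abs(tr$T %*% v - v)), 1e-12)
    expect_equal(v, eigen_stationary(tr$T), tolerance = 1e-10)
  }

  # the power-iteration path must agree with the direct solve, including
  # on the periodic two-node chain
  two <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_equal(stationary_distribution(two, dense_n = 0, tol = 1e-10),
               c(A = 0.5, B = 0.5))
  tr <- transition_matrix(build_network(random_games(6, seed = 3)))
  expect_equal(stationary_distribution(tr$T, dense_n = 0, tol = 1e-10),
               stationary_distribution(tr$T), tolerance = 1e-8)
})

test_that("tie chain is rated all-equal and the triangle transitively", {
  for (eps in c(0.5, 1, 2)) {
    r <- tidy(walkrank(tie_chain(), epsilon = eps))
    expect_equal(max(r$rating) - min(r$rating), 0)
    expect_equal(r$rank, rep(2, 3))
  }
  r <- tidy(walkrank(transitive_triangle()))
  expect_equal(r$team, c("A", "B", "C"))
  expect_true(all(diff(r$rating) < 0))
  # regularizer choice does not reorder a decisive fixture
  for (eps in c(0.5, 2)) {
    expect_equal(tidy(walkrank(transitive_triangle(), epsilon = eps))$team,
                 c("A", "B", "C"))
  }
})

test_that("strength is exactly weakness of the transposed network", {
  g <- random_games(6, n_extra = 8, seed = 21)
  swapped <- g
  swapped$score_a <- g$score_b
  swapped$score_b <- g$score_a
  net <- build_network(g)
  net_t <- build_network(swapped)
  s <- transition_matrix(net, direction = "toward_stronger")
  w_t <- transition_matrix(net_t, direction = "toward_loser")
  expect_identical(s$T, w_t$T)

  # hence transposing every score flips the combined rating's sign and
  # exactly reverses the rank order
  r <- tidy(walkrank(g))
  r_t <- tidy(walkrank(swapped))
  merged <- merge(r, r_t, by = "team")
  expect_equal(merged$rating.x, -merged$rating.y)
  n <- nrow(merged)
  expect_equal(merged$rank.x, n + 1 - merged$rank.y)
})

test_that("ratings are equivariant under relabeling of competitors", {
  g <- random_games(6, n_extra = 8, seed = 5)
  teams <- sort(unique(c(g$team_a, g$team_b)))
  map <- setNames(sprintf("Z%02d", rev(seq_along(teams))), teams)
  r1 <- tidy(walkrank(g))
  r2 <- tidy(walkrank(relabel_games(g, map)))
  r2$team <- names(map)[match(r2$team, map)]
  merged <- merge(r1, r2, by = "team")
  expect_equal(merged$rating.x, merged$rating.y)
  expect_equal(merged$rank.x, merged$rank.y)
})

test_that("disconnected networks are rated per component with node-share scaling", {
  # two disjoint pairs: each component's occupancy sums to its node share
  g <- as_game_table(data.frame(
    round = 1, team_a = c("A", "C"), score_a = c(2, 1),
    team_b = c("B", "D"), score_b = c(0, 1)
  ))
  r <- tidy(walkrank(g))
  expect_equal(sum(r$weakness), 1)
  expect_equal(sum(r$strength), 1)
  expect_equal(sum(r$weakness[r$team %in% c("A", "B")]), 0.5)
  # an unplayed roster team is an isolated component rated dead even
  r2 <- tidy(walkrank(g, teams = c("A", "B", "C", "D", "E")))
  expect_equal(r2$rating[r2$team == "E"], 0)
  # the teleportation alternative still yields a probability vector
  r3 <- tidy(walkrank(g, teleport = 0.15))
  expect_equal(sum(r3$weakness), 1)
  expect_true(all(r3$weakness > 0))
})

test_that("lazy global normalization separates the degenerate two-team network", {
  g <- as_game_table(data.frame(round = 1, team_a = "A", score_a = 3,
                                team_b = "B", score_b = 0))
  per_col <- tidy(walkrank(g))
  expect_equal(per_col$rating, c(0, 0))   # bare 2-cycle cannot separate them
  lazy <- tidy(walkrank(g, normalization = "lazy"))
  expect_gt(lazy$rating[lazy$team == "A"], lazy$rating[lazy$team == "B"])
})

test_that("jackknife errors match direct leave-one-out recomputation", {
  # single game: the (n-1)/n factor zeroes everything
  one <- as_game_table(data.frame(round = 1, team_a = "A", score_a = 2,
                                  team_b = "B", score_b = 1))
  expect_equal(jackknife_errors(one)$std.error, c(0, 0))

  # fully symmetric fixture: equal errors by symmetry
  sym <- as_game_table(data.frame(round = 1:2, team_a = "A", score_a = c(1, 0),
                                  team_b = "B", score_b = c(1, 0)))
  err <- jackknife_errors(sym)
  expect_equal(err$std.error[1], err$std.error[2])

  # 4-team, 6-game round-robin: brute-force oracle recomputes every
  # leave-one-out rating through the public interface
  g <- random_games(4, n_extra = 2, seed = 9)
  stopifnot(nrow(g) == 6)
  teams <- sort(unique(c(g$team_a, g$team_b)))
  reps <- sapply(seq_len(nrow(g)), function(i) {
    r <- tidy(walkrank(g[-i, ], teams = teams))
    r$rating[order(r$team)]
  })
  bar <- rowMeans(reps)
  expected <- sqrt(5 / 6 * rowSums((reps - bar)^2))
  expect_equal(jackknife_errors(g)$std.error, unname(expected))
})
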