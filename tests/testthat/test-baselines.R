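test_that("win-loss margins and the net-points tie breaker order teams", {
  # records 2-0, 1-1, 0-2
  g <- as_game_table(data.frame(
    round = 1, team_a = c("A", "A", "B"), score_a = 1,
    team_b = c("B", "C", "C"), score_b = 0
  ))
  wl <- winloss_rating(g)
  expect_equal(wl$margin, c(2, 0, -2))

  # two 1-1 teams, net points +3 vs -3: the former ranks higher
  g2 <- as_game_table(data.frame(
    round = 1,
    team_a = c("A", "A", "B", "B"), score_a = c(4, 1, 1, 0),
    team_b = c("C", "D", "D", "C"), score_b = c(0, 2, 0, 4)
  ))
  wl2 <- winloss_rating(g2)
  expect_equal(wl2$margin[wl2$team %in% c("A", "B")], c(0, 0))
  expect_equal(wl2$net_points[wl2$team == "A"], 3)
  expect_gt(wl2$rating[wl2$team == "A"], wl2$rating[wl2$team == "B"])

  # no games: everyone identically (0, 0)
  wl0 <- winloss_rating(g[0, ], teams = c("A", "B"))
  expect_equal(wl0$rating, c(0, 0))
})

test_that("Colley ratings solve the strictly diagonally dominant system", {
  empty <- tie_chain()[0, ]
  expect_equal(colley_rating(empty, teams = c("A", "B", "C"))$rating,
               rep(0.5, 3))

  one <- as_game_table(data.frame(round = 1, team_a = "A", score_a = 1,
                                  team_b = "B", score_b = 0))
  expect_equal(colley_rating(one)$rating, c(5 / 8, 3 / 8))

  # conservation: the mean rating is 1/2 on any fixture
  for (seed in 1:10) {
    g <- random_games(6, n_extra = 10, seed = seed, rounds = 3)
    expect_equal(mean(colley_rating(g)$rating), 0.5)
  }
})

test_that("Park-Newman reduces to wins-losses as alpha -> 0 and credits paths", {
  g <- transitive_round_robin(5)   # distinct margins 4, 2, 0, -2, -4
  pn <- park_newman_rating(g, alpha = 1e-10)
  wl <- winloss_rating(g)
  expect_equal(order(-pn$rating), order(-wl$margin))

  # all-tie network: perfect symmetry, every score zero
  ties <- as_game_table(data.frame(round = 1, team_a = c("A", "B", "A"),
                                   score_a = 1, team_b = c("B", "C", "C"),
                                   score_b = 1))
  expect_equal(park_newman_rating(ties)$rating, rep(0, 3))

  # win path A -> B -> C: A's generalized wins contain the alpha-weighted
  # indirect win over C (series expansion to second order)
  path <- as_game_table(data.frame(round = 1, team_a = c("A", "B"),
                                   score_a = 1, team_b = c("B", "C"),
                                   score_b = 0))
  a <- 0.01
  pn <- park_newman_rating(path, alpha = a)
  expect_equal(pn$win_score[pn$team == "A"], 1 + a, tolerance = 1e-6)

  # a win cycle has spectral radius 1: alpha must stay below 1
  cyc <- as_game_table(data.frame(round = 1, team_a = c("A", "B", "C"),
                                  score_a = 1, team_b = c("B", "C", "A"),
                                  score_b = 0))
  expect_error(park_newman_rating(cyc, alpha = 10), "spectral")
})

test_that("PageRank occupancy is a probability vector marking the big loser", {
  g <- random_games(6, n_extra = 8, seed = 13)
  pr <- pagerank_weakness(g)
  expect_equal(sum(pr$occupancy), 1)
  expect_true(all(pr$occupancy > 0))

  # no edges at all: uniform occupancy
  ties <- as_game_table(data.frame(round = 1, team_a = "A", score_a = 0,
                                   team_b = "B", score_b = 0))
  pr0 <- pagerank_weakness(ties, weighted = FALSE, teams = c("A", "B", "C"))
  expect_equal(pr0$occupancy, rep(1 / 3, 3))

  # star of losses: the team that lost to everyone is visited most
  star <- as_game_table(data.frame(round = 1, team_a = c("A", "B", "C"),
                                   score_a = 2, team_b = "Z", score_b = 0))
  prs <- pagerank_weakness(star)
  expect_equal(prs$team[which.max(prs$occupancy)], "Z")

  expect_error(pagerank_weakness(g, alpha = 1.2), "alpha")
})

test_that("all five methods are relabel-equivariant and agree on a strict hierarchy", {
  g <- transitive_round_robin(5)
  methods <- c("dnrw", "winloss", "colley", "parknewman", "pagerank")
  for (m in methods) {
    r <- rate_teams(g, method = m)
    expect_equal(r$team, sprintf("T%02d", 1:5), label = m)
    expect_equal(r$rank, 1:5, label = m)
  }

  g2 <- random_games(5, n_extra = 6, seed = 17)
  teams <- sort(unique(c(g2$team_a, g2$team_b)))
  map <- setNames(sprintf("Q%02d", rev(seq_along(teams))), teams)
  for (m in methods) {
    r1 <- rate_teams(g2, method = m)
    r2 <- rate_teams(relabel_games(g2, map), method = m)
    r2$team <- names(map)[match(r2$team, map)]
    merged <- merge(r1, r2, by = "team")
    expect_equal(merged$rating.x, merged$rating.y, label = m)
  }
})
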