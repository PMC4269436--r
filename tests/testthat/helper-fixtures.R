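# Shared fixtures and independent oracles.

# three-team tie chain A-B-C (two scoreless draws): the canonical
# degree-bias example -- all three teams ought to be rated equal
tie_chain <- function() {
  as_game_table(data.frame(
    round = 1L, team_a = c("A", "B"), score_a = 0,
    team_b = c("B", "C"), score_b = 0
  ))
}

# strict transitive triangle: A beats B, B beats C, A beats C, all 2:0
transitive_triangle <- function() {
  as_game_table(data.frame(
    round = 1L,
    team_a = c("A", "B", "A"), score_a = 2,
    team_b = c("B", "C", "C"), score_b = 0
  ))
}

# strictly transitive complete round-robin: Ti beats Tj (i < j) 1:0
transitive_round_robin <- function(n) {
  pairs <- t(utils::combn(n, 2))
  as_game_table(data.frame(
    round = 1L,
    team_a = sprintf("T%02d", pairs[, 1]), score_a = 1,
    team_b = sprintf("T%02d", pairs[, 2]), score_b = 0
  ))
}

# random connected fixture: a ring of games guarantees one component,
# extra random pairings and integer scores on top
random_games <- function(n_teams, n_extra = n_teams, seed = 1,
                         max_score = 5, rounds = 1) {
  set.seed(seed)
  teams <- sprintf("T%02d", seq_len(n_teams))
  ring <- data.frame(team_a = teams,
                     team_b = teams[c(seq_len(n_teams)[-1], 1)])
  extra <- if (n_extra > 0) {
    idx <- replicate(n_extra, sample(n_teams, 2))
    data.frame(team_a = teams[idx[1, ]], team_b = teams[idx[2, ]])
  } else NULL
  g <- rbind(ring, extra)
  g$round <- sample(rounds, nrow(g), replace = TRUE)
  g$score_a <- sample(0:max_score, nrow(g), replace = TRUE)
  g$score_b <- sample(0:max_score, nrow(g), replace = TRUE)
  as_game_table(g)
}

# dense eigendecomposition oracle for the stationary vector: the
# eigenvector of the eigenvalue closest to 1, made real and normalized
eigen_stationary <- function(Tm) {
  e <- eigen(Tm)
  i <- which.min(abs(e$values - 1))
  stopifnot(abs(e$values[i] - 1) < 1e-8)
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(v, colnames(Tm))
}

# relabel the teams of a game table through a named map
relabel_games <- function(games, map) {
  games$team_a <- unname(map[games$team_a])
  games$team_b <- unname(map[games$team_b])
  as_game_table(games)
}
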