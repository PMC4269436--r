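#' Win-loss differential with net-points tie breaker
#'
#' The simplest rater: teams are ordered by their win-loss margin
#' (wins minus losses; draws contribute nothing), and teams with equal
#' margins are separated by the net points (points for minus points
#' against) scored over the season. This is the official ranking scheme of
#' several football leagues and the natural baseline for any rater.
#'
#' @param games A game table.
#' @param teams Optional full roster.
#' @return A tibble with columns `team`, `margin`, `net_points`, and
#'   `rating` (a single number ordering `(margin, net_points)`
#'   lexicographically; teams equal on both get equal ratings).
#' @export
winloss_rating <- function(games, teams = NULL) {
  out <- team_records(games, teams = teams)
  out$margin <- out$wins - out$losses
  span <- 2 * (max(abs(out$net_points), 1) + 1)
  out$rating <- out$margin + out$net_points / span
  out[, c("team", "margin", "net_points", "rating")]
}

#' Colley's matrix rating
#'
#' Solves the Colley linear system: `C r = b` with
#' `C = 2 I + diag(games played) - (head-to-head counts)` and
#' `b_i = 1 + (wins_i - losses_i)/2`. The system is strictly diagonally
#' dominant, hence always uniquely solvable; with no games every rating is
#' 1/2, and the mean rating is 1/2 on any fixture.
#'
#' @param games A game table.
#' @param teams Optional full roster.
#' @return A tibble with columns `team` and `rating` (each in (0, 1)).
#' @export
colley_rating <- function(games, teams = NULL) {
  net <- build_network(games, teams = teams)
  out <- team_records(games, teams = net$teams)
  n <- length(net$teams)
  if (n == 0) return(tibble::tibble(team = character(), rating = numeric()))
  C <- diag(2 + out$games, n) - net$games_played
  b <- 1 + (out$wins - out$losses) / 2
  tibble::tibble(team = net$teams, rating = as.vector(solve(C, b)))
}

#' Park-Newman generalized wins-losses
#'
#' A directional Katz-style rater: a team is credited not only with its
#' direct wins but, attenuated by `alpha` per step, with the wins of the
#' teams it beat, and so on along all directed win paths. The win score is
#' `(I - alpha A)^{-1} A 1` on the win-count matrix `A` (`A[i, j]` = games
#' `i` beat `j`; draws carry no path), the loss score is the same series on
#' the transpose, and the rating is their difference. As `alpha -> 0` the
#' ordering reduces to plain wins minus losses.
#'
#' @param games A game table.
#' @param alpha Attenuation per path step; must be below `1/lambda_max` of
#'   the win matrix. Default `0.9 / lambda_max` (0 when the win matrix is
#'   nilpotent-free of cycles, i.e. `lambda_max = 0`, where any alpha works).
#' @param teams Optional full roster.
#' @return A tibble with columns `team`, `win_score`, `loss_score`,
#'   `rating`.
#' @export
park_newman_rating <- function(games, alpha = NULL, teams = NULL) {
  games <- as_game_table(games)
  A <- win_matrix(games, teams = teams)
  n <- nrow(A)
  if (n == 0) {
    return(tibble::tibble(team = character(), win_score = numeric(),
                          loss_score = numeric(), rating = numeric()))
  }
  lam <- if (n > 0 && any(A > 0)) max(abs(eigen(A, only.values = TRUE)$values)) else 0
  if (is.null(alpha)) alpha <- if (lam > 0) 0.9 / lam else 0.1
  if (lam > 0 && alpha >= 1 / lam) {
    rlang::abort(sprintf(
      "alpha = %g is not below the spectral bound 1/lambda_max = %g", alpha, 1 / lam
    ))
  }
  ones <- rep(1, n)
  w <- solve(diag(n) - alpha * A, A %*% ones)
  l <- solve(diag(n) - alpha * t(A), t(A) %*% ones)
  tibble::tibble(
    team = rownames(A),
    win_score = as.vector(w),
    loss_score = as.vector(l),
    rating = as.vector(w - l)
  )
}

# A[i, j] = number of games i beat j (draws contribute nothing)
win_matrix <- function(games, teams = NULL) {
  games <- as_game_table(games)
  seen <- union(games$team_a, games$team_b)
  if (is.null(teams)) teams <- seen
  teams <- sort(unique(as.character(teams)))
  A <- matrix(0, length(teams), length(teams), dimnames = list(teams, teams))
  for (g in seq_len(nrow(games))) {
    i <- match(games$team_a[g], teams); j <- match(games$team_b[g], teams)
    if (games$score_a[g] > games$score_b[g]) A[i, j] <- A[i, j] + 1
    if (games$score_b[g] > games$score_a[g]) A[j, i] <- A[j, i] + 1
  }
  A
}

#' PageRank occupancy read as weakness
#'
#' The classical damped random walk on winner-to-loser edges: with
#' probability `alpha` the walker follows an outgoing edge (so it drifts
#' toward losers), with probability `1 - alpha` it jumps to a uniformly
#' random node. Because edges point at losers, the stationary occupancy is
#' read as a team's *weakness*: the strongest team is the one visited
#' least.
#'
#' @param games A game table.
#' @param alpha Damping factor in (0, 1); default 0.85.
#' @param weighted If `TRUE` (default) edges are weighted by cumulative
#'   points scored; if `FALSE`, by win counts only.
#' @param teams Optional full roster.
#' @return A tibble with columns `team`, `occupancy` (sums to 1) and
#'   `rating` (`-occupancy`, so that higher means stronger).
#' @export
pagerank_weakness <- function(games, alpha = 0.85, weighted = TRUE,
                              teams = NULL) {
  if (alpha <= 0 || alpha >= 1) rlang::abort("alpha must lie strictly in (0, 1)")
  M <- if (weighted) build_network(games, teams = teams)$W
       else win_matrix(games, teams = teams)
  n <- nrow(M)
  if (n == 0) {
    return(tibble::tibble(team = character(), occupancy = numeric(),
                          rating = numeric()))
  }
  g <- igraph::graph_from_adjacency_matrix(M, mode = "directed", weighted = TRUE)
  pr <- igraph::page_rank(g, damping = alpha,
                          weights = igraph::E(g)$weight)$vector
  tibble::tibble(team = rownames(M), occupancy = as.vector(pr),
                 rating = -as.vector(pr))
}

#' Rate teams with any of the five methods
#'
#' Unified front door over the degree-neutralized random walk (`"dnrw"`)
#' and the four comparison methods, returning a common rating-row schema so
#' that methods can be compared, predicted with, and plotted uniformly.
#'
#' @param games A game table.
#' @param method One of `"dnrw"`, `"winloss"`, `"colley"`, `"parknewman"`,
#'   `"pagerank"`.
#' @param through_round Use only games up to this round.
#' @param teams Optional full roster.
#' @param ... Method-specific options: `epsilon`, `normalization`,
#'   `teleport` (dnrw); `alpha` (parknewman, pagerank); `weighted`
#'   (pagerank).
#' @return A tibble with columns `team`, `rating`, `rank` (descending,
#'   ties averaged) and `method`.
#' @examples
#' season <- simulate_season(n_teams = 6, seed = 1)
#' rate_teams(season, method = "colley")
#' @export
rate_teams <- function(games, method = c("dnrw", "winloss", "colley",
                                         "parknewman", "pagerank"),
                       through_round = NULL, teams = NULL, ...) {
  method <- match.arg(method)
  games <- as_game_table(games)
  if (!is.null(through_round)) {
    games <- dplyr::filter(games, .data$round <= through_round)
  }
  out <- switch(
    method,
    dnrw = tidy(walkrank(games, teams = teams, ...))[, c("team", "rating")],
    winloss = winloss_rating(games, teams = teams)[, c("team", "rating")],
    colley = colley_rating(games, teams = teams),
    parknewman = park_newman_rating(games, teams = teams, ...)[, c("team", "rating")],
    pagerank = pagerank_weakness(games, teams = teams, ...)[, c("team", "rating")]
  )
  out <- dplyr::arrange(out, .data$team)
  out$rank <- rank(-out$rating, ties.method = "average")
  out$method <- method
  dplyr::arrange(out, .data$rank, .data$team)
}
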