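#' Construct and validate a table of game records
#'
#' A game table is the package's primary input: one row per contest, with a
#' positive integer round (matchweek), two distinct competitor IDs and two
#' non-negative scores. All rating and evaluation functions accept a game
#' table as their first argument, so calls chain with the pipe.
#'
#' @param x A data frame with columns `round`, `team_a`, `score_a`,
#'   `team_b`, `score_b` (extra columns are kept).
#' @return A tibble with class `game_table` prepended, columns coerced to
#'   the canonical types (`round` integer, teams character, scores numeric).
#' @examples
#' as_game_table(data.frame(
#'   round = 1, team_a = "A", score_a = 2, team_b = "B", score_b = 1
#' ))
#' @export
as_game_table <- function(x) {
  required <- c("round", "team_a", "score_a", "team_b", "score_b")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    rlang::abort(paste0(
      "game table is missing column(s): ", paste(missing, collapse = ", ")
    ))
  }
  out <- tibble::as_tibble(x)
  out$round <- as.integer(out$round)
  out$team_a <- as.character(out$team_a)
  out$team_b <- as.character(out$team_b)
  out$score_a <- as.numeric(out$score_a)
  out$score_b <- as.numeric(out$score_b)
  validate_games(out)
  if (any(out$score_a != floor(out$score_a) | out$score_b != floor(out$score_b))) {
    rlang::warn("non-integer scores found; treating them as aggregated point totals")
  }
  class(out) <- c("game_table", class(out))
  out
}

validate_games <- function(games) {
  bad <- which(games$team_a == games$team_b)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "record %d: team_a and team_b are both '%s' (a competitor cannot play itself)",
      bad[1], games$team_a[bad[1]]
    ))
  }
  bad <- which(games$score_a < 0 | games$score_b < 0 |
                 is.na(games$score_a) | is.na(games$score_b))
  if (length(bad) > 0) {
    rlang::abort(sprintf("record %d: scores must be non-negative numbers", bad[1]))
  }
  bad <- which(is.na(games$round) | games$round < 1)
  if (length(bad) > 0) {
    rlang::abort(sprintf("record %d: round must be a positive integer", bad[1]))
  }
  invisible(games)
}

#' Accumulate games into a competition network
#'
#' Builds the weighted directed competition network: nodes are competitors,
#' and the edge weight `W[i, j]` is the cumulative points competitor `i`
#' scored against `j` over every included game (repeated fixtures are
#' summed). A symmetric count matrix tracks how many times each pair met.
#'
#' @param games A game table (see [as_game_table()]); any data frame with
#'   the five canonical columns works.
#' @param through_round If given, only games with `round <= through_round`
#'   are included (cumulative mid-season network).
#' @param teams Optional character vector forcing the node set, e.g. the
#'   full league roster so that early-season networks keep not-yet-seen
#'   teams as isolated nodes. Must contain every team in the included games.
#' @return An object of class `competition_network`: a list with `teams`
#'   (lexicographically ordered IDs), `W` (cumulative score matrix,
#'   zero diagonal), `games_played` (symmetric pair-count matrix), and `m`
#'   (total number of contests).
#' @examples
#' g <- as_game_table(data.frame(
#'   round = 1, team_a = "A", score_a = 2, team_b = "B", score_b = 1
#' ))
#' net <- build_network(g)
#' net$W
#' @export
build_network <- function(games, through_round = NULL, teams = NULL) {
  games <- as_game_table(games)
  if (!is.null(through_round)) {
    stopifnot(through_round >= 1)
    games <- dplyr::filter(games, .data$round <= through_round)
  }
  seen <- union(games$team_a, games$team_b)
  if (is.null(teams)) {
    teams <- seen
  } else if (!all(seen %in% teams)) {
    rlang::abort(paste0(
      "games mention teams outside the supplied roster: ",
      paste(setdiff(seen, teams), collapse = ", ")
    ))
  }
  teams <- sort(unique(as.character(teams)))
  n <- length(teams)
  W <- matrix(0, n, n, dimnames = list(teams, teams))
  G <- matrix(0L, n, n, dimnames = list(teams, teams))
  if (nrow(games) > 0) {
    ia <- match(games$team_a, teams)
    ib <- match(games$team_b, teams)
    for (g in seq_len(nrow(games))) {
      W[ia[g], ib[g]] <- W[ia[g], ib[g]] + games$score_a[g]
      W[ib[g], ia[g]] <- W[ib[g], ia[g]] + games$score_b[g]
      G[ia[g], ib[g]] <- G[ia[g], ib[g]] + 1L
      G[ib[g], ia[g]] <- G[ib[g], ia[g]] + 1L
    }
  }
  structure(
    list(teams = teams, W = W, games_played = G, m = nrow(games)),
    class = "competition_network"
  )
}

#' @export
print.competition_network <- function(x, ...) {
  cat(sprintf(
    "<competition_network: %d teams, %d games, connectance %s>\n",
    length(x$teams), x$m,
    if (length(x$teams) >= 2) format(connectance(x), digits = 4) else "NA"
  ))
  invisible(x)
}

#' Connectance of a competition network
#'
#' The number of contests divided by the number of competitor pairs,
#' `m / (N(N-1)/2)`. A single complete round-robin has connectance 1; a
#' double round-robin (every pair meets twice) has connectance 2; sparse
#' schedules such as a 256-game, 32-team season sit near 0.5.
#'
#' @param net A `competition_network`.
#' @return A non-negative number (may exceed 1 for repeated fixtures).
#' @export
connectance <- function(net) {
  stopifnot(inherits(net, "competition_network"))
  n <- length(net$teams)
  if (n < 2) rlang::abort("connectance requires at least 2 competitors")
  net$m / (n * (n - 1) / 2)
}

#' Distinct-opponent degree of each competitor
#'
#' The degree used by the degree-neutralizing discount: the number of
#' distinct opponents a competitor has faced, regardless of how many times
#' each pairing was repeated.
#'
#' @param net A `competition_network`.
#' @return A tibble with columns `team` and `degree`.
#' @export
opponent_degrees <- function(net) {
  stopifnot(inherits(net, "competition_network"))
  tibble::tibble(
    team = net$teams,
    degree = as.integer(rowSums(net$games_played > 0))
  )
}

degree_vector <- function(net) {
  k <- rowSums(net$games_played > 0)
  names(k) <- net$teams
  k
}

#' Per-team season records
#'
#' Wins, losses, draws, games played and points for/against per team,
#' computed straight from the game list (the cumulative network loses
#' individual game outcomes).
#'
#' @param games A game table.
#' @param teams Optional full roster (teams without games get zero rows).
#' @return A tibble with one row per team: `team`, `games`, `wins`,
#'   `losses`, `draws`, `points_for`, `points_against`, `net_points`.
#' @export
team_records <- function(games, teams = NULL) {
  games <- as_game_table(games)
  seen <- union(games$team_a, games$team_b)
  if (is.null(teams)) teams <- seen
  teams <- sort(unique(as.character(teams)))
  long <- dplyr::bind_rows(
    dplyr::transmute(games, team = .data$team_a,
                     pf = .data$score_a, pa = .data$score_b),
    dplyr::transmute(games, team = .data$team_b,
                     pf = .data$score_b, pa = .data$score_a)
  )
  long <- dplyr::mutate(
    long,
    win = as.integer(.data$pf > .data$pa),
    loss = as.integer(.data$pf < .data$pa),
    draw = as.integer(.data$pf == .data$pa)
  )
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$team),
    games = dplyr::n(),
    wins = sum(.data$win), losses = sum(.data$loss), draws = sum(.data$draw),
    points_for = sum(.data$pf), points_against = sum(.data$pa),
    .groups = "drop"
  )
  out <- dplyr::left_join(tibble::tibble(team = teams), out, by = "team")
  out <- dplyr::mutate(
    out,
    dplyr::across(c("games", "wins", "losses", "draws",
                    "points_for", "points_against"),
                  ~ tidyr::replace_na(.x, 0)),
    net_points = .data$points_for - .data$points_against
  )
  dplyr::arrange(out, .data$team)
}
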