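#' Build a season schedule
#'
#' Two schedule families cover the two league topologies of interest:
#'
#' * `"round_robin"`: every pair meets exactly `r` times, arranged by the
#'   circle method so each team plays at most once per round (an odd team
#'   count gives each team one bye per cycle). Connectance is exactly `r`.
#' * `"conference"`: teams are split into equal divisions; each team plays
#'   a single round-robin inside its division plus inter-division rounds
#'   (divisions paired by the circle method, teams matched by rotating
#'   index offsets) until it reaches `games_per_team` games. This emulates
#'   sparse league schedules with connectance well below 1.
#'
#' @param n_teams Number of teams (>= 2). Teams are labelled `T01`, `T02`, ...
#' @param type `"round_robin"` or `"conference"`.
#' @param r Round-robin repetitions (default 1).
#' @param divisions Number of equal divisions (conference only).
#' @param games_per_team Total games per team (conference only); must be at
#'   least the intra-division round-robin size, and extra inter-division
#'   rounds require an even number of divisions.
#' @return A tibble with columns `round`, `team_a`, `team_b`.
#' @export
make_schedule <- function(n_teams, type = c("round_robin", "conference"),
                          r = 1, divisions = NULL, games_per_team = NULL) {
  type <- match.arg(type)
  stopifnot(n_teams >= 2)
  teams <- sprintf("T%02d", seq_len(n_teams))
  if (type == "round_robin") {
    stopifnot(r >= 1)
    one <- circle_round_robin(teams)
    purrr::map_dfr(seq_len(r), function(cycle) {
      dplyr::mutate(one, round = .data$round + (cycle - 1) * max(one$round))
    })
  } else {
    if (is.null(divisions) || is.null(games_per_team)) {
      rlang::abort("conference schedules need `divisions` and `games_per_team`")
    }
    if (n_teams %% divisions != 0) {
      rlang::abort("n_teams must divide evenly into divisions")
    }
    s <- n_teams / divisions
    intra_games <- s - 1
    extra <- games_per_team - intra_games
    if (extra < 0) {
      rlang::abort(sprintf(
        "games_per_team = %d is below the intra-division round-robin (%d games)",
        games_per_team, intra_games
      ))
    }
    if (extra > 0 && divisions %% 2 != 0) {
      rlang::abort("inter-division rounds require an even number of divisions")
    }
    div_of <- rep(seq_len(divisions), each = s)
    intra <- purrr::map_dfr(seq_len(divisions), function(d) {
      circle_round_robin(teams[div_of == d])
    })
    n_intra_rounds <- max(intra$round)
    inter <- if (extra > 0) {
      pairings <- circle_round_robin(as.character(seq_len(divisions)))
      n_pair_rounds <- max(pairings$round)
      purrr::map_dfr(seq_len(extra), function(e) {
        pr <- (e - 1) %% n_pair_rounds + 1
        offset <- (e - 1) %/% n_pair_rounds
        pairs <- dplyr::filter(pairings, .data$round == pr)
        purrr::map_dfr(seq_len(nrow(pairs)), function(p) {
          da <- as.integer(pairs$team_a[p]); db <- as.integer(pairs$team_b[p])
          ta <- teams[div_of == da]; tb <- teams[div_of == db]
          tibble::tibble(
            round = n_intra_rounds + e,
            team_a = ta,
            team_b = tb[(seq_len(s) - 1 + offset) %% s + 1]
          )
        })
      })
    } else NULL
    out <- dplyr::bind_rows(intra, inter)
    dplyr::arrange(out, .data$round, .data$team_a)
  }
}

# circle method: fix the first team, rotate the rest; odd n adds a bye slot
circle_round_robin <- function(teams) {
  n <- length(teams)
  slots <- if (n %% 2 == 1) c(teams, NA) else teams
  ns <- length(slots)
  rounds <- ns - 1
  purrr::map_dfr(seq_len(rounds), function(rd) {
    idx <- c(1, ((seq_len(ns - 1) - 1 + (rd - 1)) %% (ns - 1)) + 2)
    cur <- slots[idx]
    a <- cur[seq_len(ns / 2)]
    b <- rev(cur)[seq_len(ns / 2)]
    keep <- !is.na(a) & !is.na(b)
    tibble::tibble(round = rd, team_a = pmin(a[keep], b[keep]),
                   team_b = pmax(a[keep], b[keep]))
  })
}

#' Simulate a season with known latent strengths
#'
#' Generates a full season of integer-scored games over a schedule from
#' [make_schedule()]. Scores are independent Poisson draws: team `i`
#' playing team `j` scores with mean `mu * exp(beta * (theta_i - theta_j) / 2)`
#' (and `j` the mirrored mean), so win probability rises smoothly with the
#' strength gap while upsets and ties arise naturally. Draws are taken
#' sequentially in deterministic schedule order from a single seeded
#' stream, so a truncated season is identical to the corresponding prefix
#' of the full one.
#'
#' @param n_teams Number of teams; default 20 (a league-sized field).
#' @param strengths Latent strength vector `theta` (length `n_teams`);
#'   default evenly spaced on `[-1, 1]`, assigned to teams in label order.
#' @param schedule,r,divisions,games_per_team Passed to [make_schedule()];
#'   default a double round-robin (two cycles, connectance 2).
#' @param mu Base expected score per team per game; default 1.4
#'   (association-football-like).
#' @param beta Sensitivity of expected score to the strength gap; default
#'   1.5, giving clearly separated top and bottom teams while leaving
#'   mid-table outcomes stochastic.
#' @param seed Integer seed; required for reproducibility.
#' @return A `game_table` with an attached `"strengths"` attribute (named
#'   latent strengths, the ground truth for recovery experiments).
#' @examples
#' season <- simulate_season(n_teams = 6, seed = 42)
#' head(season)
#' attr(season, "strengths")
#' @export
simulate_season <- function(n_teams = 20, strengths = NULL,
                            schedule = c("round_robin", "conference"),
                            r = 2, divisions = NULL, games_per_team = NULL,
                            mu = 1.4, beta = 1.5, seed = NULL) {
  schedule <- match.arg(schedule)
  stopifnot(mu > 0, beta >= 0)
  if (is.null(strengths)) strengths <- seq(-1, 1, length.out = n_teams)
  if (length(strengths) != n_teams) {
    rlang::abort("strengths must have length n_teams")
  }
  sched <- make_schedule(n_teams, type = schedule, r = r,
                         divisions = divisions,
                         games_per_team = games_per_team)
  sched <- dplyr::arrange(sched, .data$round, .data$team_a, .data$team_b)
  teams <- sprintf("T%02d", seq_len(n_teams))
  theta <- stats::setNames(strengths, teams)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  d <- theta[sched$team_a] - theta[sched$team_b]
  score_a <- integer(nrow(sched)); score_b <- integer(nrow(sched))
  for (g in seq_len(nrow(sched))) {   # sequential draws: prefix-stable
    score_a[g] <- stats::rpois(1, mu * exp(beta * d[g] / 2))
    score_b[g] <- stats::rpois(1, mu * exp(-beta * d[g] / 2))
  }
  out <- as_game_table(tibble::tibble(
    round = sched$round, team_a = sched$team_a, score_a = score_a,
    team_b = sched$team_b, score_b = score_b
  ))
  attr(out, "strengths") <- theta
  out
}
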