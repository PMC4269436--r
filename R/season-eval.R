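#' Cumulative weekly prediction accuracy
#'
#' Replays a season round by round: for every round `t >= 2`, each method
#' is fitted on the cumulative games through round `t - 1` and made to
#' predict every round-`t` game by picking the higher-rated team. A correct
#' pick scores 1, a wrong one 0, and a drawn game scores 1/2 regardless of
#' the pick; a game involving a team with no prior games, or two
#' equally-rated teams, also scores 1/2 (the prediction itself is a draw).
#'
#' @param games A game table spanning at least 2 rounds.
#' @param methods Character vector of method names (see [rate_teams()]).
#' @param teams Optional full roster; defaults to every team in `games`.
#' @param ... Options forwarded to [rate_teams()] (applied to every method).
#' @return A tibble with one row per (round, method): `round`, `method`,
#'   `n_games`, `correct` (summed credit), `accuracy`.
#' @seealso [aggregate_accuracy()] for the season-level figure.
#' @export
weekly_accuracy <- function(games, methods = "dnrw", teams = NULL, ...) {
  games <- as_game_table(games)
  rounds <- sort(unique(games$round))
  if (length(rounds) < 2) rlang::abort("weekly accuracy needs at least 2 rounds")
  if (is.null(teams)) teams <- sort(union(games$team_a, games$team_b))
  purrr::map_dfr(methods, function(m) {
    purrr::map_dfr(rounds[-1], function(t) {
      prior <- dplyr::filter(games, .data$round < t)
      current <- dplyr::filter(games, .data$round == t)
      ratings <- rate_teams(prior, method = m, teams = teams, ...)
      rated <- stats::setNames(ratings$rating, ratings$team)
      seen <- union(prior$team_a, prior$team_b)
      credit <- purrr::pmap_dbl(
        current[, c("team_a", "team_b", "score_a", "score_b")],
        function(team_a, team_b, score_a, score_b) {
          if (score_a == score_b) return(0.5)
          if (!(team_a %in% seen) || !(team_b %in% seen)) return(0.5)
          ra <- rated[[team_a]]; rb <- rated[[team_b]]
          if (ra == rb) return(0.5)
          predicted <- if (ra > rb) team_a else team_b
          actual <- if (score_a > score_b) team_a else team_b
          as.numeric(predicted == actual)
        }
      )
      tibble::tibble(round = t, method = m, n_games = nrow(current),
                     correct = sum(credit),
                     accuracy = sum(credit) / nrow(current))
    })
  })
}

#' Season-aggregate prediction accuracy
#'
#' Total correct credit over total games predicted, per method, from the
#' per-round series of [weekly_accuracy()].
#'
#' @param series Output of [weekly_accuracy()].
#' @return A tibble with columns `method` and `accuracy`.
#' @export
aggregate_accuracy <- function(series) {
  dplyr::summarise(
    dplyr::group_by(series, .data$method),
    accuracy = sum(.data$correct) / sum(.data$n_games),
    .groups = "drop"
  )
}

#' Weekly rank-convergence series
#'
#' Tracks, for one method, how quickly the cumulative partial rankings
#' stabilize: for every round the Spearman rank correlation (average ranks
#' for ties) between the round's ranking and the final one, and the number
#' of line crossings -- pairs of teams whose relative order switched --
#' against the previous round. The final round's correlation is 1 by
#' construction.
#'
#' @param games A game table.
#' @param method Method name (see [rate_teams()]).
#' @param teams Optional full roster.
#' @param ... Options forwarded to [rate_teams()].
#' @return A tibble with columns `round`, `src` (NA when fewer than two
#'   teams are rated), `crossings` (NA for the first round).
#' @export
src_series <- function(games, method = "dnrw", teams = NULL, ...) {
  games <- as_game_table(games)
  rounds <- sort(unique(games$round))
  if (is.null(teams)) teams <- sort(union(games$team_a, games$team_b))
  rank_of <- function(through) {
    r <- rate_teams(games, method = method, through_round = through,
                    teams = teams, ...)
    r <- dplyr::arrange(r, .data$team)
    stats::setNames(r$rank, r$team)
  }
  final <- rank_of(max(rounds))
  prev <- NULL
  purrr::map_dfr(rounds, function(t) {
    cur <- rank_of(t)
    src <- if (length(cur) >= 2) {
      # an all-tied partial ranking has zero variance: SRC is undefined (NA)
      suppressWarnings(stats::cor(cur, final[names(cur)], method = "spearman"))
    } else NA_real_
    cross <- if (is.null(prev)) NA_integer_ else line_crossings(prev, cur)
    prev <<- cur
    tibble::tibble(round = t, src = src, crossings = cross)
  })
}

#' First round at which the partial ranking is close to final
#'
#' @param series Output of [src_series()].
#' @param threshold Spearman correlation threshold in (0, 1]; default 0.9.
#' @return The earliest round whose SRC meets the threshold (NA if none).
#' @export
convergence_round <- function(series, threshold = 0.9) {
  stopifnot(threshold > 0, threshold <= 1)
  hit <- series$round[!is.na(series$src) & series$src >= threshold]
  if (length(hit) == 0) NA_integer_ else min(hit)
}

#' Count line crossings between two rankings
#'
#' The number of unordered team pairs whose relative order differs between
#' two rankings of the same competitor set (discordant pairs). Pairs tied
#' in either ranking do not count. Symmetric in its arguments and invariant
#' under relabeling.
#'
#' @param rank_a,rank_b Named numeric vectors of ranks (or any scores whose
#'   order defines the ranking) over the same teams.
#' @return A non-negative integer.
#' @examples
#' line_crossings(c(A = 1, B = 2, C = 3), c(A = 3, B = 2, C = 1)) # 3
#' @export
line_crossings <- function(rank_a, rank_b) {
  if (is.null(names(rank_a)) || is.null(names(rank_b)) ||
      !setequal(names(rank_a), names(rank_b))) {
    rlang::abort("the two rankings must be named over the same competitor set")
  }
  rank_b <- rank_b[names(rank_a)]
  s1 <- sign(outer(rank_a, rank_a, "-"))
  s2 <- sign(outer(rank_b, rank_b, "-"))
  disc <- (s1 * s2) == -1
  as.integer(sum(disc[upper.tri(disc)]))
}

#' Exponential decay fit for line-crossing counts
#'
#' Fits `a * exp(-b * t)` to the per-round crossing counts by nonlinear
#' least squares on the raw counts (late-season rounds with zero crossings
#' rule out a log-linear fit). An all-zero series is returned as the
#' degenerate fit `a = 0` with `degenerate = TRUE`.
#'
#' @param crossings Numeric vector of non-negative counts.
#' @param rounds Round indices; defaults to `seq_along(crossings)`.
#' @return An `exp_fit` object with `tidy()` (term/estimate/std.error) and
#'   `glance()` (residual norm, degenerate flag) methods; fields `a`, `b`,
#'   `residual_norm`.
#' @export
fit_exponential <- function(crossings, rounds = seq_along(crossings)) {
  keep <- !is.na(crossings)
  y <- as.numeric(crossings[keep]); t <- as.numeric(rounds[keep])
  if (length(y) < 3) rlang::abort("exponential fit needs at least 3 rounds")
  if (all(y == 0)) {
    return(structure(
      list(a = 0, b = 0, residual_norm = 0, degenerate = TRUE, fit = NULL,
           data = tibble::tibble(round = t, crossings = y)),
      class = "exp_fit"
    ))
  }
  pos <- y > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(y[pos]) ~ t[pos])
    a0 <- exp(stats::coef(lf)[[1]]); b0 <- -stats::coef(lf)[[2]]
  } else {
    a0 <- max(y); b0 <- 0.1
  }
  nls_from <- function(b_start) {
    minpack.lm::nlsLM(
      y ~ a * exp(-b * t),
      start = list(a = a0, b = b_start),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    )
  }
  # an exact-fit start can present a singular Jacobian; nudge the rate
  fit <- tryCatch(nls_from(b0), error = function(e) nls_from(b0 + 1e-4))
  co <- stats::coef(fit)
  structure(
    list(a = co[["a"]], b = co[["b"]],
         residual_norm = sqrt(sum(stats::resid(fit)^2)),
         degenerate = FALSE, fit = fit,
         data = tibble::tibble(round = t, crossings = y)),
    class = "exp_fit"
  )
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("<exp_fit: degenerate (all crossings zero)>\n")
  } else {
    cat(sprintf("<exp_fit: %.4g * exp(-%.4g t), residual norm %.4g>\n",
                x$a, x$b, x$residual_norm))
  }
  invisible(x)
}

#' @method tidy exp_fit
#' @export
tidy.exp_fit <- function(x, ...) {
  if (x$degenerate) {
    return(tibble::tibble(term = c("a", "b"), estimate = c(0, 0),
                          std.error = c(NA_real_, NA_real_)))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, "Estimate"],
                 std.error = s[, "Std. Error"])
}

#' @method glance exp_fit
#' @export
glance.exp_fit <- function(x, ...) {
  tibble::tibble(a = x$a, b = x$b, residual_norm = x$residual_norm,
                 degenerate = x$degenerate, n = nrow(x$data))
}
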