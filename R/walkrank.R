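#' Gradient weights on a competition edge
#'
#' Each edge of the competition network carries a pair of complementary
#' transition weights -- the "gradient" -- derived from the cumulative
#' scores of the two competitors against each other. With the default
#' loser-seeking orientation the walker steps toward competitor `a` with
#' weight proportional to the points scored *against* `a` (plus the
#' regularizer `epsilon`), so the slope runs downhill from winner to loser
#' while still allowing upset-like uphill moves. `epsilon > 0` keeps both
#' weights strictly positive even for a scoreless tie.
#'
#' @param score_a,score_b Cumulative points the two competitors scored
#'   against each other (non-negative; vectorized).
#' @param epsilon Positive regularizer; default 1.
#' @return A tibble with columns `toward_a` and `toward_b`, each row a
#'   strictly positive pair summing to 1.
#' @examples
#' edge_gradient(2, 1) # the 1-point side attracts the larger weight
#' @export
edge_gradient <- function(score_a, score_b, epsilon = 1) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0) {
    rlang::abort("epsilon must be a single positive number")
  }
  stopifnot(all(score_a >= 0), all(score_b >= 0))
  s <- score_a + score_b + 2 * epsilon
  tibble::tibble(
    toward_a = (score_b + epsilon) / s,
    toward_b = (score_a + epsilon) / s
  )
}

#' Degree-neutralized Markov transition matrix
#'
#' Builds the column-stochastic transition matrix of the gradient random
#' walk on a competition network. The probability of the move `j -> i` is
#' proportional to the gradient weight toward `i` on edge `{i, j}`,
#' discounted by the distinct-opponent degree `k_i` of the target, then
#' normalized per column. The degree discount removes the bias by which a
#' well-connected node would be visited more (or less) often on topology
#' alone.
#'
#' @param net A `competition_network` in which every node has played at
#'   least one game (see [build_network()]); components are handled
#'   upstream by [walkrank()].
#' @param epsilon Positive gradient regularizer (default 1).
#' @param direction `"toward_loser"` (occupancy measures weakness, the
#'   default) or `"toward_stronger"` (occupancy measures strength; the
#'   gradient orientation on every edge is swapped).
#' @param normalization `"column"` (default): each column is normalized by
#'   its own factor `Z_j`. `"lazy"`: a single global normalizer with the
#'   shortfall placed on self-loops; the two readings agree on which
#'   stationary ordering they induce except on degenerate two-node
#'   networks, where only the lazy walk separates the teams.
#' @return A `walk_transition` object: list with the matrix `T` (columns
#'   sum to 1), the per-column normalizers `Z`, and the settings used.
#' @export
transition_matrix <- function(net, epsilon = 1,
                              direction = c("toward_loser", "toward_stronger"),
                              normalization = c("column", "lazy")) {
  direction <- match.arg(direction)
  normalization <- match.arg(normalization)
  stopifnot(inherits(net, "competition_network"))
  n <- length(net$teams)
  if (n < 2) rlang::abort("transition matrix requires at least 2 competitors")
  if (net$m < 1) rlang::abort("transition matrix requires at least one game")
  if (any(rowSums(net$games_played) == 0)) {
    rlang::abort(
      "every node must have played at least one game; split into components first"
    )
  }
  W <- net$W
  adj <- net$games_played > 0
  S <- W + t(W) + 2 * epsilon
  grad <- if (direction == "toward_loser") {
    (t(W) + epsilon) / S   # entry [i, j]: weight of j -> i, large when i lost
  } else {
    (W + epsilon) / S      # swapped orientation: walker prefers the winner
  }
  grad[!adj] <- 0
  k <- degree_vector(net)
  R <- grad / k            # discount by target degree (rows are targets)
  Tm <- R
  if (normalization == "column") {
    Z <- colSums(R)
    Tm <- sweep(R, 2, Z, "/")
  } else {
    Z <- rep(max(colSums(R)), n)
    Tm <- R / Z[1]
    diag(Tm) <- diag(Tm) + 1 - colSums(Tm)
  }
  structure(
    list(T = Tm, Z = Z, direction = direction, normalization = normalization,
         teams = net$teams),
    class = "walk_transition"
  )
}

#' Stationary distribution of a column-stochastic matrix
#'
#' Solves `T v = v`, `sum(v) = 1`, `v >= 0`. For moderate sizes the unique
#' stationary vector of an irreducible chain is found by a dense linear
#' solve of the balance equations; for larger matrices power iteration on
#' the half-lazy operator `(I + T)/2` is used, which shares the stationary
#' vector but converges geometrically even on periodic chains (e.g. the
#' two-node network, whose bare walk is a deterministic 2-cycle).
#'
#' @param x A `walk_transition` or a column-stochastic matrix.
#' @param tol Residual tolerance on `max(abs(T v - v))`; default 1e-12.
#' @param max_iter Iteration cap for the power method; default 1e6.
#' @param dense_n Matrices up to this size use the direct solve; default 2000.
#' @return A named probability vector.
#' @export
stationary_distribution <- function(x, tol = 1e-12, max_iter = 1e6,
                                    dense_n = 2000) {
  Tm <- if (inherits(x, "walk_transition")) x$T else as.matrix(x)
  n <- ncol(Tm)
  stopifnot(tol > 0, n >= 1)
  if (max(abs(colSums(Tm) - 1)) > 1e-8) {
    rlang::abort("matrix is not column-stochastic")
  }
  if (n == 1) return(stats::setNames(1, colnames(Tm)))
  v <- NULL
  if (n <= dense_n) {
    M <- Tm - diag(n)
    M[n, ] <- 1                      # replace one balance eq by normalization
    b <- c(rep(0, n - 1), 1)
    v <- tryCatch(solve(M, b), error = function(e) NULL)
  }
  if (is.null(v) || max(abs(Tm %*% v - v)) >= tol || any(v < -tol)) {
    L <- (Tm + diag(n)) / 2
    v <- rep(1 / n, n)
    it <- 0
    repeat {
      v_new <- as.vector(L %*% v)
      v_new <- v_new / sum(v_new)
      it <- it + 1
      if (max(abs(v_new - v)) < tol / 4 || it >= max_iter) {
        v <- v_new
        break
      }
      v <- v_new
    }
  }
  v[v < 0] <- 0
  v <- v / sum(v)
  resid <- max(abs(Tm %*% v - v))
  if (resid >= tol) {
    rlang::abort(sprintf(
      "stationary solve did not converge: residual %.3e >= tol %.3e", resid, tol
    ))
  }
  stats::setNames(as.vector(v), colnames(Tm))
}

# stationary occupancy for one walk direction, handling disconnected
# networks: each connected component gets its own chain, and its vector is
# scaled by the component's share of nodes (no teleportation by default --
# a random jump would act as an indiscriminate equalizer of nodes).
walk_occupancy <- function(net, epsilon, direction, normalization,
                           teleport = 0, tol = 1e-12, max_iter = 1e6) {
  n <- length(net$teams)
  if (teleport > 0) {
    adj <- net$games_played > 0
    tm <- matrix(1 / n, n, n)
    if (any(adj)) {
      active <- which(rowSums(adj) > 0)
      sub <- subnetwork(net, active)
      bare <- transition_matrix(sub, epsilon, direction, normalization)$T
      tm[active, active] <- bare
      tm[, active] <- (1 - teleport) * tm[, active] + teleport / n
      lone <- setdiff(seq_len(n), active)
      if (length(lone) > 0) tm[, lone] <- 1 / n
    }
    colnames(tm) <- net$teams
    return(stationary_distribution(tm, tol, max_iter))
  }
  comps <- network_components(net)
  v <- stats::setNames(numeric(n), net$teams)
  for (comp in comps) {
    share <- length(comp) / n
    if (length(comp) == 1) {
      v[comp] <- share
    } else {
      sub <- subnetwork(net, comp)
      tr <- transition_matrix(sub, epsilon, direction, normalization)
      v[comp] <- share * stationary_distribution(tr, tol, max_iter)
    }
  }
  v
}

network_components <- function(net) {
  g <- igraph::graph_from_adjacency_matrix(
    (net$games_played > 0) * 1, mode = "undirected", diag = FALSE
  )
  memb <- igraph::components(g)$membership
  split(seq_along(memb), memb)
}

subnetwork <- function(net, idx) {
  structure(
    list(
      teams = net$teams[idx],
      W = net$W[idx, idx, drop = FALSE],
      games_played = net$games_played[idx, idx, drop = FALSE],
      m = sum(net$games_played[idx, idx]) / 2
    ),
    class = "competition_network"
  )
}

#' Degree-neutralized random-walk rating
#'
#' The package's core rater. Two gradient random walks are run on the
#' cumulative competition network: a loser-seeking walk whose stationary
#' occupancy `w` measures each competitor's *weakness*, and a
#' winner-seeking walk whose occupancy `s` measures *strength*. Both walks
#' discount the probability of entering a node by its distinct-opponent
#' degree, so neither well-connected nor peripheral nodes are favored on
#' topology alone. Since neither picture is privileged, the final rating is
#' their combination `pi = s - w`; higher means stronger.
#'
#' Disconnected networks (typical in early-season weeks) are rated per
#' connected component, each component's occupancy scaled by its share of
#' nodes; set `teleport > 0` to use a PageRank-style random jump instead.
#'
#' @param games A game table (see [as_game_table()]).
#' @param epsilon Positive gradient regularizer; default 1.
#' @param through_round Use only games up to this round (cumulative rating).
#' @param teams Optional full roster (kept as isolated, zero-rated nodes if
#'   they have not played).
#' @param jackknife If `TRUE`, attach delete-one-game jackknife standard
#'   errors to the combined rating.
#' @param normalization,teleport,eig_tol,max_iter Passed to
#'   [transition_matrix()] and [stationary_distribution()].
#' @return A `walkrank` object. `tidy()` returns one row per competitor
#'   (team, weakness, strength, rating, rank and, with `jackknife = TRUE`,
#'   `std.error`), ordered strongest first with a net-points then
#'   lexicographic display tie-break; `glance()` returns one-row model
#'   facts; `autoplot()` draws the rating ladder.
#' @examples
#' season <- simulate_season(n_teams = 6, seed = 1)
#' r <- walkrank(season)
#' tidy(r)
#' @export
walkrank <- function(games, epsilon = 1, through_round = NULL, teams = NULL,
                     jackknife = FALSE, normalization = c("column", "lazy"),
                     teleport = 0, eig_tol = 1e-12, max_iter = 1e6) {
  normalization <- match.arg(normalization)
  games <- as_game_table(games)
  if (!is.null(through_round)) {
    games <- dplyr::filter(games, .data$round <= through_round)
  }
  net <- build_network(games, teams = teams)
  if (length(net$teams) == 0) rlang::abort("no competitors in the game table")
  res <- walkrank_vectors(net, epsilon, normalization, teleport,
                          eig_tol, max_iter)
  outcomes <- team_records(games, teams = net$teams)
  tbl <- tibble::tibble(
    team = net$teams,
    weakness = unname(res$weakness),
    strength = unname(res$strength),
    rating = unname(res$rating)
  )
  tbl$rank <- rank(-tbl$rating, ties.method = "average")
  tbl <- dplyr::left_join(tbl, outcomes[, c("team", "net_points")], by = "team")
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$rating),
                        dplyr::desc(.data$net_points), .data$team)
  if (jackknife) {
    err <- jackknife_errors(games, epsilon = epsilon, teams = net$teams,
                            normalization = normalization,
                            teleport = teleport, eig_tol = eig_tol,
                            max_iter = max_iter)
    tbl <- dplyr::left_join(tbl, err, by = "team")
  }
  structure(
    list(result = tbl, net = net, epsilon = epsilon,
         normalization = normalization, teleport = teleport,
         n_games = nrow(games)),
    class = "walkrank"
  )
}

walkrank_vectors <- function(net, epsilon = 1, normalization = "column",
                             teleport = 0, tol = 1e-12, max_iter = 1e6) {
  weak <- walk_occupancy(net, epsilon, "toward_loser", normalization,
                         teleport, tol, max_iter)
  strong <- walk_occupancy(net, epsilon, "toward_stronger", normalization,
                           teleport, tol, max_iter)
  list(weakness = weak, strength = strong, rating = strong - weak)
}

#' Jackknife standard errors for the combined rating
#'
#' Delete-one-game jackknife: the combined rating is recomputed on each of
#' the `n` networks with one game removed, and each competitor's error is
#' `sqrt(((n-1)/n) * sum_g (pi_i^(g) - mean_g pi_i^(g))^2)`.
#'
#' @inheritParams walkrank
#' @return A tibble with columns `team` and `std.error`.
#' @export
jackknife_errors <- function(games, epsilon = 1, teams = NULL,
                             normalization = "column", teleport = 0,
                             eig_tol = 1e-12, max_iter = 1e6) {
  games <- as_game_table(games)
  n <- nrow(games)
  if (n < 1) rlang::abort("jackknife requires at least one game")
  if (is.null(teams)) teams <- sort(union(games$team_a, games$team_b))
  reps <- vapply(seq_len(n), function(g) {
    net <- build_network(games[-g, , drop = FALSE], teams = teams)
    walkrank_vectors(net, epsilon, normalization, teleport,
                     eig_tol, max_iter)$rating
  }, numeric(length(teams)))
  reps <- matrix(reps, nrow = length(teams))   # teams x n replicates
  bar <- rowMeans(reps)
  err <- sqrt((n - 1) / n * rowSums((reps - bar)^2))
  tibble::tibble(team = sort(teams), std.error = err)
}

#' @export
print.walkrank <- function(x, ...) {
  cat(sprintf(
    "Degree-neutralized random-walk rating (%d teams, %d games, epsilon = %g)\n",
    length(x$net$teams), x$n_games, x$epsilon
  ))
  print(x$result, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @method tidy walkrank
#' @export
tidy.walkrank <- function(x, ...) x$result

#' @method glance walkrank
#' @export
glance.walkrank <- function(x, ...) {
  tibble::tibble(
    n_teams = length(x$net$teams),
    n_games = x$n_games,
    connectance = if (length(x$net$teams) >= 2) connectance(x$net) else NA_real_,
    epsilon = x$epsilon,
    normalization = x$normalization,
    teleport = x$teleport
  )
}
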