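#' Configuration for the synthetic AOP-collection generator
#'
#' The generator emulates the structure of curated AOP-Wiki collections:
#' mostly-linear pathways of 3–8 events (an MIE, one or more intermediate
#' KEs, an AO), a minority of key events shared between pathways, occasional
#' reuse of whole relationships, sporadic feedback loops, qualitative
#' weight-of-evidence labels dominated by "unspecified", and rare nonadjacent
#' flags. Defaults describe a 13-pathway collection in that regime.
#'
#' @param n_aops number of pathways to generate.
#' @param chain_length_range integer `(min, max)` events per pathway;
#'   `min >= 3` (MIE, at least one KE, AO).
#' @param p_share_ke probability that a newly placed event reuses an existing
#'   key event from an earlier pathway.
#' @param p_share_ker probability that a step reuses a whole existing
#'   relationship (both endpoints, in order).
#' @param p_feedback probability of injecting one feedback back-edge into a
#'   pathway; the back-edge never runs from a pathway's AO to its MIE, so at
#'   least one MIE-to-AO path always survives.
#' @param woe_weights named probabilities over
#'   `c("high","medium","low","unspecified")`; must sum to 1.
#' @param p_nonadjacent probability that a relationship is flagged
#'   nonadjacent.
#' @param seed root seed. Per-pathway substreams are derived from it, so
#'   appending pathways never reshuffles the ones already generated.
#' @return a validated list of class `generator_config`.
#' @export
generator_config <- function(n_aops = 13,
                             chain_length_range = c(3, 8),
                             p_share_ke = 0.25,
                             p_share_ker = 0.05,
                             p_feedback = 0.1,
                             woe_weights = c(high = 0.23, medium = 0.13,
                                             low = 0, unspecified = 0.64),
                             p_nonadjacent = 0.04,
                             seed = 1) {
  if (n_aops < 1) abort("n_aops must be positive")
  if (length(chain_length_range) != 2 || chain_length_range[1] < 3 ||
      chain_length_range[2] < chain_length_range[1]) {
    abort("chain_length_range must be (min, max) with min >= 3")
  }
  probs <- c(p_share_ke, p_share_ker, p_feedback, p_nonadjacent)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (!setequal(names(woe_weights), WOE_LEVELS)) {
    abort("woe_weights must be named high/medium/low/unspecified")
  }
  if (any(woe_weights < 0) || abs(sum(woe_weights) - 1) > 1e-8) {
    abort("woe_weights must be non-negative and sum to 1")
  }
  structure(
    list(
      n_aops = as.integer(n_aops),
      chain_length_range = as.integer(chain_length_range),
      p_share_ke = p_share_ke, p_share_ker = p_share_ker,
      p_feedback = p_feedback,
      woe_weights = woe_weights[WOE_LEVELS],
      p_nonadjacent = p_nonadjacent,
      seed = as.integer(seed)
    ),
    class = "generator_config"
  )
}

pick1 <- function(x) x[[sample.int(length(x), 1)]]

#' Generate a synthetic AOP collection
#'
#' Fully reproducible from the config's seed: pathway `i` draws from a
#' substream derived deterministically from `(seed, i)`, so the same seed
#' always yields byte-identical collections and inserting an extra pathway
#' leaves earlier ones untouched. Generated collections always pass
#' [validate_collection()] with an empty report.
#'
#' @param config a [generator_config()].
#' @return an [aop_collection()].
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  pool <- character(0)          # titles in creation order
  pool_kers <- tibble(upstream = character(0), downstream = character(0))
  counter <- 0L
  new_title <- function() {
    counter <<- counter + 1L
    sprintf("KE-%04d", counter)
  }
  rows <- vector("list", config$n_aops)

  for (i in seq_len(config$n_aops)) {
    set.seed((config$seed + 1000003 * i) %% 2147483647L)
    L <- sample.int(config$chain_length_range[2] - config$chain_length_range[1] + 1L,
                    1) + config$chain_length_range[1] - 1L
    chain <- character(L)
    # first event
    if (stats::runif(1) < config$p_share_ke && length(pool) > 0) {
      chain[1] <- pick1(pool)
    } else if (config$p_share_ke >= 1 && length(pool) == 0) {
      abort("Infeasible generator config: p_share_ke = 1 but no existing key event to reuse")
    } else {
      chain[1] <- new_title()
    }
    for (j in 2:L) {
      placed <- FALSE
      if (stats::runif(1) < config$p_share_ker) {
        cand <- pool_kers$downstream[
          pool_kers$upstream == chain[j - 1] &
            !pool_kers$downstream %in% chain
        ]
        if (length(cand) > 0) {
          chain[j] <- pick1(cand)
          placed <- TRUE
        }
      }
      if (!placed && stats::runif(1) < config$p_share_ke) {
        cand <- setdiff(pool, chain)
        if (length(cand) > 0) {
          chain[j] <- pick1(cand)
          placed <- TRUE
        } else if (config$p_share_ke >= 1) {
          abort("Infeasible generator config: p_share_ke = 1 but every existing key event is already in this chain")
        }
      }
      if (!placed) chain[j] <- new_title()
    }

    role_at <- function(pos) {
      if (pos == 1) "MIE" else if (pos == L) "AO" else "KE"
    }
    draw_woe <- function() {
      sample(WOE_LEVELS, 1, prob = config$woe_weights)
    }
    aop_rows <- lapply(2:L, function(j) {
      tibble(
        aop_id = i,
        aop_title = sprintf("Synthetic AOP %d", i),
        upstream_title = chain[j - 1], upstream_type = role_at(j - 1),
        downstream_title = chain[j], downstream_type = role_at(j),
        adjacency = if (stats::runif(1) < config$p_nonadjacent) "nonadjacent" else "adjacent",
        woe = draw_woe()
      )
    })

    if (stats::runif(1) < config$p_feedback) {
      pairs <- expand.grid(from = seq_len(L), to = seq_len(L))
      pairs <- pairs[pairs$to < pairs$from & !(pairs$from == L & pairs$to == 1), ]
      p <- pairs[sample.int(nrow(pairs), 1), ]
      aop_rows <- c(aop_rows, list(tibble(
        aop_id = i,
        aop_title = sprintf("Synthetic AOP %d", i),
        upstream_title = chain[p$from], upstream_type = role_at(p$from),
        downstream_title = chain[p$to], downstream_type = role_at(p$to),
        adjacency = "adjacent",
        woe = draw_woe()
      )))
    }

    rows[[i]] <- bind_rows(aop_rows)
    pool <- unique(c(pool, chain))
    pool_kers <- distinct(bind_rows(
      pool_kers,
      tibble(upstream = rows[[i]]$upstream_title,
             downstream = rows[[i]]$downstream_title)
    ))
  }

  aop_collection(bind_rows(rows))
}
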