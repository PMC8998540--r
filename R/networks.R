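#' Experimental condition specification
#'
#' The simulation crosses income change with three network mechanisms into
#' eight conditions:
#'
#' 1. income only;
#' 2. income + the baseline social-support covariate in the risk model;
#' 3. income + agents drop depressed ties;
#' 4. income + agents add ties;
#' 5. income + drop depressed ties + add ties;
#' 6. drop depressed ties only;
#' 7. drop depressed ties + add ties;
#' 8. add ties only.
#'
#' `p_act` is the per-step probability that an agent acts on her network
#' (1 by default: decisions are deterministic given the flags), and
#' `ties_added_per_act` how many new within-DA ties an acting agent gains.
#'
#' @param condition_id Integer 1-8.
#' @param p_act Probability an agent acts each step.
#' @param ties_added_per_act New ties per acting agent per step.
#' @return An object of class `md_condition`.
#' @export
condition_spec <- function(condition_id, p_act = 1.0,
                           ties_added_per_act = 1L) {
  stopifnot(condition_id %in% 1:8, p_act >= 0, p_act <= 1,
            ties_added_per_act >= 0)
  flags <- list(
    list(income = TRUE,  support = FALSE, remove = FALSE, add = FALSE),
    list(income = TRUE,  support = TRUE,  remove = FALSE, add = FALSE),
    list(income = TRUE,  support = FALSE, remove = TRUE,  add = FALSE),
    list(income = TRUE,  support = FALSE, remove = FALSE, add = TRUE),
    list(income = TRUE,  support = FALSE, remove = TRUE,  add = TRUE),
    list(income = FALSE, support = FALSE, remove = TRUE,  add = FALSE),
    list(income = FALSE, support = FALSE, remove = TRUE,  add = TRUE),
    list(income = FALSE, support = FALSE, remove = FALSE, add = TRUE)
  )[[condition_id]]
  structure(list(condition_id = as.integer(condition_id),
                 income_change = flags$income,
                 include_support_covariate = flags$support,
                 remove_depressed_ties = flags$remove,
                 add_ties = flags$add,
                 p_act = p_act,
                 ties_added_per_act = as.integer(ties_added_per_act)),
            class = "md_condition")
}

#' The eight experimental conditions
#'
#' @param p_act,ties_added_per_act Passed to [condition_spec()].
#' @return A list of eight [condition_spec()] objects, ids 1-8.
#' @export
condition_table <- function(p_act = 1.0, ties_added_per_act = 1L) {
  lapply(1:8, condition_spec, p_act = p_act,
         ties_added_per_act = ties_added_per_act)
}

#' One agent acts on her network
#'
#' Applies the condition's network decisions for agent `i`: first drop
#' every tie to a currently depressed agent, then add
#' `ties_added_per_act` new ties to randomly chosen same-DA agents not
#' already tied.  All edits are symmetric.  This is the single-agent
#' primitive behind [network_step()].
#'
#' @param ties List of integer tie vectors (agent indices).
#' @param i Acting agent's index.
#' @param depressed Logical vector of current depression flags.
#' @param da_members Integer vector of agent indices in `i`'s DA.
#' @param spec A [condition_spec()].
#' @return List with updated `ties` and `skipped` (1 if an addition found
#'   no eligible partner).
#' @export
act <- function(ties, i, depressed, da_members, spec) {
  skipped <- 0L
  if (spec$remove_depressed_ties && length(ties[[i]])) {
    drop <- ties[[i]][depressed[ties[[i]]]]
    if (length(drop)) {
      ties[[i]] <- setdiff(ties[[i]], drop)
      for (j in drop) ties[[j]] <- setdiff(ties[[j]], i)
    }
  }
  if (spec$add_ties && spec$ties_added_per_act > 0L) {
    eligible <- setdiff(da_members, c(i, ties[[i]]))
    if (length(eligible) == 0L) {
      skipped <- 1L
    } else {
      k <- min(spec$ties_added_per_act, length(eligible))
      new <- eligible[sample.int(length(eligible), k)]
      ties[[i]] <- c(ties[[i]], new)
      for (j in new) ties[[j]] <- c(ties[[j]], i)
    }
  }
  list(ties = ties, skipped = skipped)
}

#' One synchronous network step for the whole population
#'
#' Every agent acts with probability `p_act`, in a random order; removals
#' are applied before additions population-wide, so an agent cannot re-add
#' a tie she just dropped within the same step.  Tie symmetry is preserved
#' and `social_support_present` is refreshed from the updated tie counts.
#' The number of additions skipped for lack of an eligible partner is
#' recorded in `attr(, "n_add_skipped")`.
#'
#' @param agents Agent data frame with `ties` list-column.
#' @param spec A [condition_spec()].
#' @param depressed Logical vector of current depression flags; defaults to
#'   `agents$depressed`.
#' @return Updated `agents`.
#' @export
network_step <- function(agents, spec, depressed = agents$depressed) {
  stopifnot(inherits(spec, "md_condition"))
  n <- nrow(agents)
  if (is.null(depressed) || anyNA(depressed)) depressed <- rep(FALSE, n)
  ties <- agents$ties
  acting <- if (spec$p_act >= 1) rep(TRUE, n) else runif(n) < spec$p_act
  skipped <- 0L

  if (spec$remove_depressed_ties && any(acting)) {
    # an edge (a, b) disappears when a acts and b is depressed (or vice versa)
    for (i in which(acting)) {
      t <- ties[[i]]
      if (!length(t)) next
      drop <- t[depressed[t]]
      if (!length(drop)) next
      ties[[i]] <- setdiff(t, drop)
      for (j in drop) ties[[j]] <- setdiff(ties[[j]], i)
    }
  }

  if (spec$add_ties && spec$ties_added_per_act > 0L && any(acting)) {
    da_members <- split(seq_len(n), agents$da_id)
    da_key <- match(agents$da_id, names(da_members))
    for (i in sample(which(acting))) {
      members <- da_members[[da_key[i]]]
      eligible <- setdiff(members, c(i, ties[[i]]))
      if (length(eligible) == 0L) {
        skipped <- skipped + 1L
        next
      }
      k <- min(spec$ties_added_per_act, length(eligible))
      new <- if (length(eligible) == 1L) eligible else
        eligible[sample.int(length(eligible), k)]
      ties[[i]] <- c(ties[[i]], new)
      for (j in new) ties[[j]] <- c(ties[[j]], i)
    }
  }

  agents$ties <- ties
  agents$social_support_present <- lengths(ties) >= 1L
  attr(agents, "n_add_skipped") <- skipped
  agents
}

#' Network contribution to the depression logit
#'
#' `beta_network_size * |ties| + beta_depressed_ties * #depressed ties`.
#' With the default signs (-0.3, +0.1) a tie is protective on net even
#' when the tied agent is depressed, so dropping a depressed tie raises
#' the logit by `|beta_network_size| - |beta_depressed_ties|`.
#'
#' @param ties List of integer tie vectors (or a single integer vector).
#' @param depressed Logical vector of current depression flags.
#' @param coeffs A [coefficient_set()].
#' @return Numeric vector of logit offsets.
#' @export
network_offset <- function(ties, depressed, coeffs) {
  if (!is.list(ties)) ties <- list(ties)
  coeffs$beta_network_size * lengths(ties) +
    coeffs$beta_depressed_ties * count_depressed_ties(ties, depressed)
}
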