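#' Simulation configuration
#'
#' Collects every tunable of the synthetic-genome generator. Defaults encode
#' the study conditions the simulator is meant to emulate: neutral decay of a
#' mammalian EVE at the pangenomic mammal substitution rate of 0.0027
#' substitutions/site/My, mild lineage rate variation, a realistic indel
#' load, and conserved flanking landmark genes evolving under purifying
#' constraint (emulated as a reduced rate).
#'
#' @param model A [gtr_model()] `subst_model` for nucleotide evolution.
#' @param clock_rate Mean substitution rate, substitutions/site/My.
#' @param branch_sd Standard deviation (log scale) of per-branch lognormal
#'   rate multipliers; 0 gives a strict clock.
#' @param indel_rate Indel events per substitution (so absolute indel rate is
#'   `indel_rate * clock_rate` events/site/My).
#' @param indel_mean_len Mean indel length, nt (geometric distribution).
#' @param landmark_n Landmark genes on each side of the element.
#' @param landmark_aa Length of each landmark protein, aa.
#' @param landmark_rate_scale Rate multiplier for landmark gene sites
#'   (< 1 emulates purifying selection on the host genes).
#' @param eve_rate_scale Rate multiplier for element sites (1 = neutral).
#' @param spacer_len Intergenic spacer between locus features, nt.
#' @param insertion_age Age (My) at which the element entered the locus;
#'   `NULL` places it at the midpoint of the insertion branch.
#' @param loss_prob Per-taxon probability that a carrier lineage loses the
#'   element (applied by [apply_losses()]).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(model = gtr_model(),
                       clock_rate = 0.0027,
                       branch_sd = 0.1,
                       indel_rate = 0.1,
                       indel_mean_len = 3,
                       landmark_n = 3L,
                       landmark_aa = 450L,
                       landmark_rate_scale = 0.15,
                       eve_rate_scale = 1,
                       spacer_len = 6000L,
                       insertion_age = NULL,
                       loss_prob = 0) {
  stopifnot(inherits(model, "subst_model"),
            clock_rate >= 0, branch_sd >= 0, indel_rate >= 0,
            indel_mean_len >= 1, landmark_n >= 1L, landmark_aa >= 30L,
            landmark_rate_scale >= 0, eve_rate_scale >= 0, spacer_len >= 0,
            loss_prob >= 0, loss_prob <= 1,
            is.null(insertion_age) || insertion_age > 0)
  out <- as.list(environment())
  class(out) <- "sim_config"
  out
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: rate", x$clock_rate, "subs/site/My, branch_sd",
      x$branch_sd, ", indels", x$indel_rate, "x subs\n")
  invisible(x)
}

# plain-list echo of a config for serialization (model reduced to params)
config_echo <- function(config) {
  list(
    model = list(label = config$model$label,
                 freq = as.numeric(config$model$freq),
                 alpha = config$model$alpha, ncat = config$model$ncat),
    clock_rate = config$clock_rate, branch_sd = config$branch_sd,
    indel_rate = config$indel_rate, indel_mean_len = config$indel_mean_len,
    landmark_n = config$landmark_n, landmark_aa = config$landmark_aa,
    landmark_rate_scale = config$landmark_rate_scale,
    eve_rate_scale = config$eve_rate_scale, spacer_len = config$spacer_len,
    insertion_age = config$insertion_age, loss_prob = config$loss_prob
  )
}
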