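#' Clock model specification
#'
#' @param kind `"strict"` or `"ucln"` (uncorrelated lognormal relaxed
#'   clock: per-branch rate multipliers with mean 1).
#' @param rate Initial mean substitution rate (subs/site/My).
#' @param sd Lognormal standard deviation of branch multipliers (ucln only).
#' @return List of class `clock_model`.
#' @export
clock_model <- function(kind = c("strict", "ucln"), rate = 0.003, sd = 0.3) {
  kind <- match.arg(kind)
  stopifnot(rate > 0, sd >= 0)
  structure(list(kind = kind, rate = rate, sd = sd), class = "clock_model")
}

#' MCMC configuration
#'
#' @param generations Chain length (proposals).
#' @param sample_every Sampling interval.
#' @param burnin Burn-in fraction in \[0, 1); proposal step sizes are tuned
#'   toward 20-40% acceptance during burn-in, then frozen.
#' @param seed Integer seed.
#' @param root_max Upper bound of the uniform root-age prior (My).
#' @param rate_prior_meanlog,rate_prior_sdlog Diffuse lognormal prior on the
#'   mean clock rate (default: median 0.003 subs/site/My, wide).
#' @param estimate_model Sample GTR exchangeabilities and frequencies; if
#'   `FALSE` they stay fixed at the supplied model's values.
#' @param estimate_alpha Sample the gamma shape (if the model has > 1
#'   category).
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(generations = 20000L, sample_every = 20L,
                        burnin = 0.25, seed = 1L, root_max = 500,
                        rate_prior_meanlog = log(0.003),
                        rate_prior_sdlog = 1,
                        estimate_model = TRUE, estimate_alpha = TRUE) {
  stopifnot(generations >= sample_every, burnin >= 0, burnin < 1)
  structure(as.list(environment()), class = "mcmc_config")
}

# log prior density of a sampler state (-Inf encodes constraint violation)
#' Log prior density of a dating-model state
#'
#' Sum of the calibration normal log-densities, the uniform root-age prior,
#' the lognormal clock-rate prior, lognormal branch-multiplier priors (ucln),
#' and diffuse priors on the substitution-model parameters. Returns `-Inf`
#' when any child age reaches or exceeds its parent's (constraint
#' violation), so invalid states are rejected rather than erroring.
#'
#' @param state List with `ages`, `rate`, and optionally `alpha`, `exch`,
#'   `mults` (as built inside [mcmc_run()]).
#' @param ctx Prior context built by [mcmc_run()] (calibration nodes, root
#'   bounds, clock settings); see the source for fields.
#' @return Scalar log density.
#' @export
prior_logdensity <- function(state, ctx) {
  ages <- state$ages
  # ordering constraint: every child strictly younger than its parent
  if (any(ages[ctx$edge[, 2]] >= ages[ctx$edge[, 1]])) return(-Inf)
  root_age <- ages[ctx$root]
  if (root_age < ctx$root_min || root_age > ctx$root_max) return(-Inf)
  lp <- -log(ctx$root_max - ctx$root_min)
  if (length(ctx$calib_nodes)) {
    lp <- lp + sum(dnorm(ages[ctx$calib_nodes], ctx$calib_means,
                         ctx$calib_sds, log = TRUE))
  }
  lp <- lp + dlnorm(state$rate, ctx$rate_meanlog, ctx$rate_sdlog, log = TRUE)
  if (!is.null(state$alpha)) {
    lp <- lp + dlnorm(state$alpha, 0, 1.5, log = TRUE)
  }
  if (!is.null(state$exch)) {
    lp <- lp + sum(dexp(state$exch, 1, log = TRUE))
  }
  if (!is.null(state$mults)) {
    s <- ctx$clock_sd
    lp <- lp + sum(dlnorm(state$mults, -s^2 / 2, s, log = TRUE))
  }
  lp
}

#' Node-calibrated Bayesian molecular dating by MCMC
#'
#' Metropolis-Hastings sampling of node ages, the mean clock rate, branch
#' rate multipliers (relaxed clock), and substitution-model parameters on a
#' fixed topology, with normal calibration priors on clade ages. Moves:
#' node-age uniform slide within its (oldest child, parent) bounds,
#' reflected root-age slide, scale moves on rate/alpha/exchangeabilities,
#' frequency transfer, and branch-multiplier scaling. Supplying
#' `alignment = NULL` samples from the prior (data-free run).
#'
#' @param alignment Named character vector / matrix of aligned sequences
#'   (tips of `dating_tree$phylo`), or `NULL` for a prior-only run.
#' @param dating_tree A [build_dating_tree()] `dating_tree` (fixed topology
#'   and initial ages).
#' @param calibrations List of [calibration()] objects.
#' @param clock A [clock_model()].
#' @param model A `subst_model` (initial values; GTR frequencies are kept
#'   fixed at their initial values unless `estimate_model`).
#' @param config An [mcmc_config()].
#' @return Object of class `posterior_trace`: `samples` (matrix, one row per
#'   sample: lp, loglik, rate, alpha, node ages), `acceptance` per move,
#'   `config`, `node_columns` (map node id -> column), `crown_nodes`.
#' @export
mcmc_run <- function(alignment, dating_tree, calibrations,
                     clock = clock_model(), model = gtr_model(),
                     config = mcmc_config()) {
  stopifnot(inherits(dating_tree, "dating_tree"),
            inherits(config, "mcmc_config"))
  ph <- dating_tree$phylo
  ntip <- ape::Ntip(ph)
  nnode <- ph$Nnode
  root <- ntip + 1L
  edge <- ph$edge
  po <- ape::postorder(ph)
  data_free <- is.null(alignment)
  pat <- if (!data_free) compress_alignment(alignment, model, ph$tip.label)

  calib_nodes <- vapply(calibrations, function(cl) {
    as.integer(ape::getMRCA(ph, cl$taxa))
  }, 1L)
  calib_means <- vapply(calibrations, `[[`, 1, "mean")
  calib_sds <- vapply(calibrations, `[[`, 1, "sd")
  root_min <- if (length(calib_means)) max(calib_means) else 0
  ctx <- list(edge = edge, root = root, root_min = root_min,
              root_max = config$root_max,
              calib_nodes = calib_nodes, calib_means = calib_means,
              calib_sds = calib_sds,
              rate_meanlog = config$rate_prior_meanlog,
              rate_sdlog = config$rate_prior_sdlog,
              clock_sd = clock$sd)

  # children of each internal node (to bound age slides)
  kids <- split(edge[, 2], edge[, 1])
  parent_of <- integer(ntip + nnode)
  parent_of[edge[, 2]] <- edge[, 1]

  state <- list(ages = dating_tree$ages, rate = clock$rate)
  state$ages[root] <- max(state$ages[root],
                          root_min + 0.05 * (config$root_max - root_min))
  # re-space internal ages proportionally if the root moved up
  est_alpha <- config$estimate_alpha && model$ncat > 1L &&
    is.finite(model$alpha)
  if (est_alpha) state$alpha <- model$alpha
  est_model <- config$estimate_model && model$label == "GTR"
  relaxed <- clock$kind == "ucln"
  if (relaxed) state$mults <- rep(1, nrow(edge))
  if (est_model && is.null(state$exch)) state$exch <- rep(1, 5)

  if (est_model && !is.null(model$exch)) {
    state$exch <- unname(model$exch[1:5] / model$exch[6])
  }
  cur_model <- model
  # changing alpha only rescales the category rates; Q is untouched
  refresh_alpha <- function(m, alpha) {
    m$alpha <- alpha
    m$cat_rates <- gamma_category_rates(alpha, m$ncat)
    m
  }

  loglik <- function(st, m) {
    if (data_free) return(0)
    elen <- (st$ages[edge[, 1]] - st$ages[edge[, 2]]) * st$rate
    if (relaxed) elen <- elen * st$mults
    ll <- pruning_loglik_compressed(ph, elen, pat, m)
    ll
  }

  internal <- (ntip + 1L):(ntip + nnode)
  non_root <- setdiff(internal, root)
  # two age-move flavors: a bound-wide uniform slide (good for vague nodes)
  # and a tuned reflected window slide (good for tightly calibrated nodes,
  # whose bounds can span a hundredfold of their posterior width)
  moves <- c("age", "age_win", "root", "rate")
  if (est_alpha) moves <- c(moves, "alpha")
  if (est_model) moves <- c(moves, "exch", "freq")
  if (relaxed) moves <- c(moves, "mult")
  move_w <- c(age = max(1, length(non_root) / 2),
              age_win = max(1, length(non_root) / 2),
              root = 2, rate = 2, alpha = 1, exch = 1, freq = 1,
              mult = if (relaxed) max(1, nrow(edge) / 4) else 0)[moves]
  step <- c(age_win = 4, root = 20, rate = 0.4, alpha = 0.5, exch = 0.5,
            freq = 0.05, mult = 0.4)
  step_max <- c(age_win = config$root_max, root = config$root_max - root_min,
                rate = 3, alpha = 3, exch = 3, freq = 0.2, mult = 3)
  acc <- prop <- setNames(numeric(length(moves)), moves)

  cur_lp_prior <- prior_logdensity(state, ctx)
  stopifnot(is.finite(cur_lp_prior))
  cur_ll <- loglik(state, cur_model)
  n_samp <- config$generations %/% config$sample_every
  nodecols <- paste0("age_", internal)
  cols <- c("lp", "loglik", "rate",
            if (est_alpha) "alpha",
            if (est_model) paste0("exch_", c("AC", "AG", "AT", "CG", "CT")),
            nodecols)
  samples <- matrix(NA_real_, n_samp, length(cols),
                    dimnames = list(NULL, cols))
  burn_end <- floor(config$generations * config$burnin)

  set.seed(config$seed)
  si <- 0L
  for (it in seq_len(config$generations)) {
    mv <- sample(moves, 1L, prob = move_w)
    prop[mv] <- prop[mv] + 1
    cand <- state
    log_hastings <- 0
    valid <- TRUE
    model_cand <- cur_model
    if (mv == "age") {
      nd <- if (length(non_root) == 1L) non_root else sample(non_root, 1L)
      lo <- max(cand$ages[kids[[as.character(nd)]]])
      hi <- cand$ages[parent_of[nd]]
      if (hi <= lo) valid <- FALSE else cand$ages[nd] <- runif(1, lo, hi)
    } else if (mv == "age_win") {
      nd <- if (length(non_root) == 1L) non_root else sample(non_root, 1L)
      lo <- max(cand$ages[kids[[as.character(nd)]]])
      hi <- cand$ages[parent_of[nd]]
      if (hi <= lo) {
        valid <- FALSE
      } else {
        x <- cand$ages[nd] + runif(1, -step["age_win"], step["age_win"])
        span <- hi - lo
        x <- abs(x - lo) %% (2 * span)
        cand$ages[nd] <- lo + if (x > span) 2 * span - x else x
      }
    } else if (mv == "root") {
      lo <- max(cand$ages[kids[[as.character(root)]]])
      lo <- max(lo, ctx$root_min)
      x <- cand$ages[root] + runif(1, -step["root"], step["root"])
      # reflect into (lo, root_max)
      span <- ctx$root_max - lo
      x <- abs(x - lo) %% (2 * span)
      x <- lo + ifelse(x > span, 2 * span - x, x)
      cand$ages[root] <- x
    } else if (mv == "rate") {
      f <- exp(runif(1, -step["rate"], step["rate"]))
      cand$rate <- cand$rate * f
      log_hastings <- log(f)
    } else if (mv == "alpha") {
      f <- exp(runif(1, -step["alpha"], step["alpha"]))
      cand$alpha <- cand$alpha * f
      log_hastings <- log(f)
      model_cand <- refresh_alpha(cur_model, cand$alpha)
    } else if (mv == "exch") {
      i <- sample.int(5L, 1L)
      f <- exp(runif(1, -step["exch"], step["exch"]))
      cand$exch[i] <- cand$exch[i] * f
      log_hastings <- log(f)
      model_cand <- refresh_alpha(
        gtr_model(exch = c(cand$exch, 1), freq = cur_model$freq,
                  alpha = if (est_alpha) cand$alpha else model$alpha,
                  ncat = model$ncat),
        if (est_alpha) cand$alpha else model$alpha)
    } else if (mv == "freq") {
      fr <- cur_model$freq
      ij <- sample.int(4L, 2L)
      d <- runif(1, -step["freq"], step["freq"])
      fr[ij[1]] <- fr[ij[1]] + d
      fr[ij[2]] <- fr[ij[2]] - d
      if (any(fr <= 0.01)) valid <- FALSE else model_cand <- refresh_alpha(
        gtr_model(exch = if (est_model) c(cand$exch, 1) else rep(1, 6),
                  freq = fr,
                  alpha = if (est_alpha) cand$alpha else model$alpha,
                  ncat = model$ncat),
        if (est_alpha) cand$alpha else model$alpha)
    } else if (mv == "mult") {
      i <- sample.int(length(cand$mults), 1L)
      f <- exp(runif(1, -step["mult"], step["mult"]))
      cand$mults[i] <- cand$mults[i] * f
      log_hastings <- log(f)
    }
    lp_prior <- if (valid) prior_logdensity(cand, ctx) else -Inf
    if (is.finite(lp_prior)) {
      ll <- loglik(cand, model_cand)
      a <- (lp_prior + ll) - (cur_lp_prior + cur_ll) + log_hastings
      if (log(runif(1)) < a) {
        state <- cand
        cur_lp_prior <- lp_prior
        cur_ll <- ll
        cur_model <- model_cand
        acc[mv] <- acc[mv] + 1
      }
    }
    # tune scale moves during burn-in
    if (it <= burn_end && it %% 200L == 0L) {
      for (m2 in intersect(names(step), moves)) {
        if (prop[m2] >= 20) {
          r <- acc[m2] / prop[m2]
          step[m2] <- min(step[m2] * exp(0.5 * (r - 0.3)), step_max[m2])
          acc[m2] <- prop[m2] <- 0
        }
      }
    }
    if (it %% config$sample_every == 0L) {
      si <- si + 1L
      samples[si, ] <- c(cur_lp_prior + cur_ll, cur_ll, state$rate,
                         if (est_alpha) state$alpha,
                         if (est_model) state$exch,
                         state$ages[internal])
    }
  }
  rate_acc <- acc / pmax(prop, 1)
  zero <- names(rate_acc)[prop > 50 & acc == 0]
  if (length(zero)) {
    warning("zero acceptance after tuning for move(s): ",
            paste(zero, collapse = ", "))
  }
  structure(list(samples = samples[seq_len(si), , drop = FALSE],
                 acceptance = rate_acc, config = config,
                 node_columns = setNames(nodecols, internal),
                 crown_nodes = dating_tree$crown_nodes,
                 root = root),
            class = "posterior_trace")
}

#' @export
print.posterior_trace <- function(x, ...) {
  cat("posterior_trace:", nrow(x$samples), "samples x",
      ncol(x$samples), "columns\n")
  invisible(x)
}
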