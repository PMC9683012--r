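# Sequence evolution engine.
#
# A sequence "state" is a list of parallel vectors:
#   seq   integer nucleotide codes 1..4 (A,C,G,T)
#   anc   ancestral coordinate (0-based) of each position, NA for material
#         inserted after the root
#   scale per-site rate multiplier (feature-specific, e.g. landmark genes)
#   cat   per-site discrete-gamma category index
# States evolve down a tree by GTR+Gamma substitutions (vectorized per
# parent-state/category/scale group) plus geometric-length indels.

new_state <- function(seq, scale = rep(1, length(seq)), cat = NULL,
                      model = NULL) {
  n <- length(seq)
  if (is.null(cat)) {
    ncat <- if (is.null(model)) 1L else model$ncat
    cat <- sample.int(ncat, n, replace = TRUE)
  }
  list(seq = seq, anc = seq_len(n) - 1L, scale = scale, cat = cat)
}

# substitute along one branch of length `blen` (subs/site at scale 1)
substitute_state <- function(state, model, blen) {
  if (blen <= 0 || length(state$seq) == 0L) return(state)
  scale_vals <- unique(state$scale)
  scale_idx <- match(state$scale, scale_vals)
  ncat <- model$ncat
  gcode <- state$cat + ncat * (scale_idx - 1L)
  groups <- sort(unique(gcode))
  cum <- array(0, c(length(groups), 4L, 3L))
  for (k in seq_along(groups)) {
    code <- groups[k]
    r <- model$cat_rates[(code - 1L) %% ncat + 1L] *
      scale_vals[(code - 1L) %/% ncat + 1L]
    P <- if (r > 0) prob_matrix(model, blen, r) else diag(4)
    cum[k, , ] <- t(apply(P, 1, cumsum))[, 1:3]
  }
  gidx <- match(gcode, groups)
  state$seq <- cpp_substitute(state$seq, gidx, cum,
                              runif(length(state$seq)))
  state
}

# apply indels along a branch: expected count = indel_rate_abs * L, split
# evenly between insertions and deletions, geometric lengths (mean given).
# Placement probability is proportional to the per-site rate scale, so
# features under purifying constraint (scale < 1) are spared indels the
# same way they are spared substitutions.
indel_state <- function(state, n_events, mean_len, model) {
  L <- length(state$seq)
  if (n_events <= 0L || L < 2L) return(state)
  is_ins <- runif(n_events) < 0.5
  lens <- rgeom(n_events, prob = 1 / mean_len) + 1L
  pos <- if (all(state$scale == state$scale[1])) {
    sample.int(L, n_events, replace = TRUE)
  } else {
    sample.int(L, n_events, replace = TRUE, prob = state$scale)
  }
  keep <- rep(TRUE, L)
  for (k in which(!is_ins)) {
    keep[pos[k]:min(L, pos[k] + lens[k] - 1L)] <- FALSE
  }
  # insertions: block k of length lens[k] goes right after position pos[k];
  # interleave surviving base positions and inserted blocks by sort keys
  # (base position p has key p, the i-th residue of a block after p has key
  # p + i/(len+1))
  ins_at <- pos[is_ins]
  ins_len <- lens[is_ins]
  n_ins <- sum(ins_len)
  if (n_ins == 0L) {
    return(list(seq = state$seq[keep], anc = state$anc[keep],
                scale = state$scale[keep], cat = state$cat[keep]))
  }
  frac <- sequence(ins_len) / (rep(ins_len, ins_len) + 1)
  keys <- c(as.numeric(which(keep)), rep(ins_at, ins_len) + frac)
  new_seq <- c(state$seq[keep],
               sample.int(4L, n_ins, replace = TRUE, prob = model$freq))
  new_anc <- c(state$anc[keep], rep(NA_integer_, n_ins))
  new_scale <- c(state$scale[keep], rep(1, n_ins))
  new_cat <- c(state$cat[keep],
               sample.int(model$ncat, n_ins, replace = TRUE))
  ord <- order(keys)
  list(seq = new_seq[ord], anc = new_anc[ord], scale = new_scale[ord],
       cat = new_cat[ord])
}

# Evolve a root state down a tree given as an edge table (preorder rows:
# parent, child, duration). Returns a list of tip states indexed by node id,
# plus the per-edge rate multipliers used.
#
# clock_rate converts durations (My) into substitutions/site; branch_mults
# is a numeric vector aligned with edge rows (lognormal multipliers).
evolve_tree <- function(edges, root_id, root_state, model, clock_rate,
                        branch_mults, indel_rate = 0, indel_mean_len = 3) {
  states <- list()
  states[[as.character(root_id)]] <- root_state
  for (i in seq_len(nrow(edges))) {
    par <- as.character(edges$parent[i])
    ch <- as.character(edges$child[i])
    blen <- edges$duration[i] * clock_rate * branch_mults[i]
    st <- substitute_state(states[[par]], model, blen)
    if (indel_rate > 0 && blen > 0) {
      # event count scales with the summed site rates, so constrained
      # features contribute proportionally fewer indels
      n_ev <- rpois(1, indel_rate * blen * sum(st$scale))
      st <- indel_state(st, n_ev, indel_mean_len, model)
    }
    states[[ch]] <- st
  }
  states
}

# draw per-edge lognormal rate multipliers (mean 1)
draw_branch_mults <- function(n, branch_sd) {
  if (branch_sd <= 0) return(rep(1, n))
  rlnorm(n, meanlog = -branch_sd^2 / 2, sdlog = branch_sd)
}

# map an ancestral-coordinate interval [s, e) (0-based) into a state's own
# coordinates; returns c(start, end) 0-based half-open (end <= start when
# the interval was wholly deleted)
map_interval <- function(state, s, e) {
  hit <- which(!is.na(state$anc) & state$anc >= s & state$anc < e)
  if (!length(hit)) {
    # anchor at the nearest surviving position for a zero-length interval
    left <- which(!is.na(state$anc) & state$anc < s)
    at <- if (length(left)) max(left) else 0L
    return(c(at, at))
  }
  c(min(hit) - 1L, max(hit))
}

# columns of the "true" multiple alignment over ancestral coordinates
# [s, e): one row per state, '-' where the ancestral position was deleted;
# inserted material is omitted (it has no ancestral column)
true_alignment_rows <- function(states, s, e) {
  cols <- s:(e - 1L)
  t(vapply(states, function(st) {
    row <- rep("-", length(cols))
    ok <- !is.na(st$anc) & st$anc >= s & st$anc < e
    row[st$anc[ok] - s + 1L] <- NT_CHARS[st$seq[ok]]
    row
  }, character(length(cols))))
}
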