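#' Default 12-taxon mammal-like host tree
#'
#' A calibrated placental-like species tree used throughout the synthetic
#' experiments: ten placentals plus marsupial and monotreme outgroups, crown
#' placentals at 102 My, the placental-marsupial split at 172 My and the
#' root at 187 My (TimeTree-like ages).
#'
#' @return Newick string.
#' @export
default_host_newick <- function() {
  paste0("((((((human:29,macaque:29):61,(mouse:82,rabbit:82):8):6,",
         "(hedgehog:80,(dog:76,cow:76):4):16):6,",
         "((elephant:60,manatee:60):39,armadillo:99):3):70,",
         "opossum:172):15,platypus:187);")
}

#' @rdname default_host_newick
#' @export
default_carrier_taxa <- function() {
  c("human", "macaque", "mouse", "rabbit", "hedgehog", "dog", "cow",
    "elephant", "manatee", "armadillo")
}

#' Landmark set and core probes of a simulated locus
#'
#' The simulator records the ancestral protein sequences of the landmark
#' genes and element genes; these serve as the curated landmark set and the
#' core-protein probe panel when screening the simulated genomes.
#'
#' @param ancestral An [simulate_ancestral_locus()] `ancestral_locus`.
#' @return [landmark_set()] / named character vector of probes.
#' @export
sim_landmark_set <- function(ancestral) {
  pr <- ancestral$proteins
  up <- grep("^LMU", names(pr), value = TRUE)
  dn <- grep("^LMD", names(pr), value = TRUE)
  landmark_set(unlist(pr[up]), unlist(pr[dn]))
}

#' @rdname sim_landmark_set
#' @export
sim_core_probes <- function(ancestral) {
  unlist(ancestral$proteins[ancestral$template$genes$name])
}

#' Screen simulated genomes for element presence (hit-based method)
#'
#' Runs the full synteny workflow per taxon: landmark location, orthologous
#' region definition, translated core-probe search, and presence calling.
#'
#' @param sim An [evolve_locus()] `eve_simulation`.
#' @param locus Locus name used in the calls.
#' @param smat A [scoring_matrix()].
#' @param threshold Presence E-value threshold.
#' @param landmark_evalue Landmark detection threshold.
#' @param probes Core probes (default: the simulated ancestral proteins).
#' @param landmarks Landmark set (default: simulated ancestral landmarks).
#' @return List: `calls` (`data.frame` taxon/locus/method/state), `details`
#'   (per-taxon `presence_call`s).
#' @export
screen_presence <- function(sim, locus = "locus", smat = scoring_matrix(),
                            threshold = 1e-5, landmark_evalue = 1e-3,
                            probes = sim_core_probes(sim$ancestral),
                            landmarks = sim_landmark_set(sim$ancestral)) {
  details <- list()
  rows <- list()
  for (tx in sim$tree$taxa) {
    subject <- taxon_sequence(sim, tx)
    loc <- locate_landmarks(subject, landmarks, smat,
                            max_evalue = landmark_evalue)
    region <- define_ortho_region(loc, nchar(subject),
                                  expected_aa = max(nchar(probes)))
    call <- call_presence(region, subject, probes, smat,
                          threshold = threshold)
    call$arrangement_ok <- check_arrangement(call$hit_groups,
                                             sim$ancestral$template)
    details[[tx]] <- call
    rows[[tx]] <- data.frame(taxon = tx, locus = locus, method = "hits",
                             state = call$state, stringsAsFactors = FALSE)
  }
  list(calls = do.call(rbind, rows), details = details)
}

#' Alignment-based presence calls for a simulated locus
#'
#' The synthetic stand-in for the whole-genome-alignment route: a taxon is
#' called present when at least `min_cover` of the element's alignment
#' columns are non-gap in that taxon's row of the locus alignment.
#'
#' @param sim An `eve_simulation`.
#' @param locus Locus name.
#' @param min_cover Minimum non-gap fraction over element columns.
#' @return `data.frame` of calls (method `"alignment"`).
#' @export
alignment_presence <- function(sim, locus = "locus", min_cover = 0.2) {
  ei <- sim$ancestral$eve_interval
  m <- true_alignment(sim, ei[1], ei[2])
  cover <- rowMeans(m != "-")
  data.frame(taxon = rownames(m), locus = locus, method = "alignment",
             state = ifelse(cover >= min_cover, "present", "absent"),
             stringsAsFactors = FALSE)
}

#' Pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Global seed; every stage derives its own seed from it.
#' @param host_newick Calibrated host tree (Newick, branch lengths in My).
#' @param carrier_clade Taxa whose stem branch receives the insertions.
#' @param loci Locus names (two paralogous insertions by default).
#' @param template Shared [eve_template()] of the ancestral element.
#' @param sim A [sim_config()].
#' @param element_root_age Age of the element ancestor (paralogue split),
#'   My.
#' @param loss_prob Per-taxon element loss probability applied per locus.
#' @param date_gene Element gene used for dating and the neutrality test.
#' @param generations,sample_every,burnin MCMC settings.
#' @param calibration_sd Calibration standard deviation (My).
#' @param n_null Null regions for the neutrality test.
#' @param presence_threshold Presence E-value threshold.
#' @param stages Stages to run, in dependency order.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("paleoeve_run_"),
                            seed = 1L,
                            host_newick = default_host_newick(),
                            carrier_clade = default_carrier_taxa(),
                            loci = c("locusA", "locusB"),
                            template = eve_template(),
                            sim = sim_config(),
                            element_root_age = 250,
                            loss_prob = 0,
                            date_gene = "POLB",
                            generations = 20000L, sample_every = 20L,
                            burnin = 0.25, calibration_sd = 2,
                            n_null = 100L,
                            presence_threshold = 1e-5,
                            stages = c("simulate", "synteny", "date",
                                       "neutral", "report")) {
  stopifnot(length(loci) %in% 1:2, loss_prob >= 0, loss_prob <= 1)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline on synthetic data
#'
#' simulate -> synteny/presence -> calibrated dating -> neutrality test ->
#' report, executed in dependency order with per-stage seeds derived from
#' the global seed. Any stage failure halts the run; stages that are
#' toggled off cause downstream stages that need their outputs to refuse to
#' run.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: per-stage outputs plus a
#'   `reports` list of `StageReport`-style entries (stage, outputs,
#'   warnings).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(config_to_list(config),
                   file.path(config$out_dir, "run_config.yaml"))
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(stage, msg) {
    line <- sprintf("[%s] %s: %s", stage, "info", msg)
    cat(line, "\n", file = log_path, append = TRUE)
    message(line)
  }
  res <- list(config = config, reports = list())
  report <- function(stage, outputs, note = "") {
    res$reports[[stage]] <<- list(stage = stage, outputs = outputs,
                                  note = note)
  }
  st <- config$stages

  if ("simulate" %in% st) {
    logf("simulate", "generating synthetic loci")
    host <- build_host_tree(config$host_newick)
    branch <- branch_above(host, config$carrier_clade)
    sims <- list()
    for (i in seq_along(config$loci)) {
      locus <- config$loci[i]
      anc <- simulate_ancestral_locus(config$sim, config$template,
                                      seed = derive_seed(config$seed, locus),
                                      eve_seed = config$seed)
      sim <- evolve_locus(host, anc, branch,
                          seed = derive_seed(config$seed, paste0("ev_", locus)),
                          element_root_age = config$element_root_age)
      if (config$loss_prob > 0) {
        sim <- apply_losses(sim, config$loss_prob,
                            seed = derive_seed(config$seed,
                                               paste0("loss_", locus)))
      }
      dir_i <- file.path(config$out_dir, paste0("sim_", locus))
      write_simulation(sim, dir_i)
      sims[[locus]] <- sim
    }
    res$host <- host
    res$sims <- sims
    report("simulate", file.path(config$out_dir,
                                 paste0("sim_", config$loci)))
  }

  if ("synteny" %in% st) {
    if (is.null(res$sims)) stop("stage 'synteny' needs stage 'simulate'")
    logf("synteny", "screening genomes for the element")
    calls <- list(); details <- list()
    for (locus in config$loci) {
      sc <- screen_presence(res$sims[[locus]], locus,
                            threshold = config$presence_threshold)
      calls[[locus]] <- rbind(sc$calls,
                              alignment_presence(res$sims[[locus]], locus))
      details[[locus]] <- sc$details
    }
    pm <- build_presence_matrix(do.call(rbind, calls))
    res$presence <- pm
    res$presence_details <- details
    res$method_comparison <- compare_methods(pm, pm, "hits", "alignment")
    pm_file <- file.path(config$out_dir, "presence_matrix.tsv")
    write_tsv(pm$calls, pm_file)
    hits_file <- file.path(config$out_dir, "hit_report.tsv")
    write_tsv(hit_report(res), hits_file)
    report("synteny", c(pm_file, hits_file))
  }

  if ("date" %in% st) {
    if (is.null(res$presence)) stop("stage 'date' needs stage 'synteny'")
    logf("date", "calibrated relaxed-clock dating of the marker gene")
    gene <- config$date_gene
    carriers <- lapply(config$loci, function(locus) {
      calls <- res$presence$calls
      calls$taxon[calls$locus == locus & calls$method == "hits" &
                    calls$state == "present"]
    })
    names(carriers) <- config$loci
    stopifnot(all(lengths(carriers) >= 2L))
    alns <- lapply(config$loci, function(locus) {
      sim <- res$sims[[locus]]
      a <- sim$ancestral$anno
      g <- a[a$name == gene, ]
      m <- true_alignment(sim, g$start, g$end, taxa = carriers[[locus]])
      rownames(m) <- paste(rownames(m), locus, sep = "|")
      m
    })
    merged <- if (length(alns) == 2L) {
      merge_alignments(alns[[1]], alns[[2]])
    } else alns[[1]]
    merged <- trim_columns(merged, 0.8)
    res$dating_alignment <- merged
    dt <- build_dating_tree(res$host, carriers,
                            root_age_init = config$element_root_age)
    cals <- host_calibrations(res$host, carriers, sd = config$calibration_sd)
    trc <- mcmc_run(apply(merged, 1, paste, collapse = ""), dt, cals,
                    clock_model("strict"), gtr_model(alpha = 1),
                    mcmc_config(generations = config$generations,
                                sample_every = config$sample_every,
                                burnin = config$burnin,
                                seed = derive_seed(config$seed, "mcmc")))
    res$trace <- trc
    res$dating_summary <- node_age_summary(trc, config$burnin)
    res$min_ages <- lapply(config$loci, function(locus) {
      min_age_from_presence(res$host, res$presence, locus, "hits")
    })
    names(res$min_ages) <- config$loci
    trace_file <- file.path(config$out_dir, "trace.tsv")
    write_tsv(as.data.frame(trc$samples), trace_file)
    sum_file <- file.path(config$out_dir, "dating_summary.tsv")
    write_tsv(res$dating_summary, sum_file)
    report("date", c(trace_file, sum_file))
  }

  if ("neutral" %in% st) {
    if (is.null(res$sims)) stop("stage 'neutral' needs stage 'simulate'")
    logf("neutral", "neutrality test against noncoding null regions")
    res$neutrality <- list()
    for (locus in config$loci) {
      sim <- res$sims[[locus]]
      a <- sim$ancestral$anno
      g <- a[a$name == config$date_gene, ]
      aln <- true_alignment(sim, 0L, length(sim$ancestral$seq),
                            taxa = names(which(sim$truth$present)))
      exclude <- a[a$type %in% c("landmark", "eve"), c("start", "end")]
      res$neutrality[[locus]] <- neutrality_test(
        aln, c(g$start, g$end), exclude, n_null = config$n_null,
        seed = derive_seed(config$seed, paste0("ks_", locus)))
    }
    ks_file <- file.path(config$out_dir, "ks_report.tsv")
    write_tsv(ks_report(res), ks_file)
    report("neutral", ks_file)
  }

  if ("report" %in% st) {
    logf("report", "writing summary report")
    rep_file <- make_report(res, file.path(config$out_dir, "report.md"))
    report("report", rep_file)
  }
  class(res) <- "pipeline_result"
  res
}

config_to_list <- function(config) {
  out <- unclass(config)
  out$sim <- config_echo(config$sim)
  out$template <- list(genes = config$template$genes,
                       tir_len = config$template$tir_len,
                       spacer_len = config$template$spacer_len)
  out
}

# Fig-style per-taxon hit table: probe intervals, stops, frameshifts
hit_report <- function(res) {
  rows <- list()
  for (locus in names(res$presence_details)) {
    for (tx in names(res$presence_details[[locus]])) {
      call <- res$presence_details[[locus]][[tx]]
      for (nm in names(call$hit_groups)) {
        g <- call$hit_groups[[nm]]
        ann <- call$annotations[[nm]]
        rows[[length(rows) + 1L]] <- data.frame(
          locus = locus, taxon = tx, probe = nm,
          start = min(g$hsps$sstart) + 1L, end = max(g$hsps$send),
          strand = if (g$strand > 0) "+" else "-",
          evalue = g$best_evalue,
          query_cover = round(g$query_cover, 1),
          n_stops = nrow(ann$stops),
          stop_positions = paste(ann$stops$pos + 1L, collapse = ","),
          n_frameshifts = nrow(ann$frameshifts),
          frameshift_positions = paste(ann$frameshifts$pos + 1L,
                                       collapse = ","),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(locus = character(0), taxon = character(0),
                      probe = character(0)))
  }
  do.call(rbind, rows)
}

ks_report <- function(res) {
  do.call(rbind, lapply(names(res$neutrality), function(locus) {
    nt <- res$neutrality[[locus]]
    data.frame(locus = locus, D = nt$ks$statistic, p_value = nt$ks$p_value,
               method = nt$ks$method,
               pooled_p = nt$ks_pooled$p_value,
               eve_mean = mean(nt$samples$eve),
               null_mean = mean(nt$samples$null),
               stringsAsFactors = FALSE)
  }))
}

#' Write the pipeline summary report
#'
#' A Markdown report with three blocks: the presence matrix, the per-taxon
#' hit/inactivation table, and the dating summary (root and per-locus MRCA
#' ages with 95% HPD), plus the neutrality verdict (marked "not run" when
#' the stage was skipped).
#'
#' @param res A `pipeline_result` (possibly with stages missing).
#' @param path Output file.
#' @return The path, invisibly.
#' @export
make_report <- function(res, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(c(...), con)
  w("# Element authentication and dating report", "")
  w("## Presence matrix")
  if (!is.null(res$presence)) {
    for (meth in unique(res$presence$calls$method)) {
      w("", paste0("### method: ", meth), "")
      m <- presence_states(res$presence, meth)
      w(paste(c("taxon", colnames(m)), collapse = "\t"))
      for (i in seq_len(nrow(m))) {
        w(paste(c(rownames(m)[i], m[i, ]), collapse = "\t"))
      }
    }
    if (!is.null(res$method_comparison) && nrow(res$method_comparison)) {
      w("", "Method-discordant calls:")
      w(paste(capture.output(print(res$method_comparison)), collapse = "\n"))
    }
  } else w("", "(empty: synteny stage not run)")
  w("", "## Hits and inactivating mutations")
  if (!is.null(res$presence_details)) {
    hr <- hit_report(res)
    if (nrow(hr)) {
      w(paste(colnames(hr), collapse = "\t"))
      for (i in seq_len(nrow(hr))) {
        w(paste(unlist(hr[i, ]), collapse = "\t"))
      }
    } else w("(no hits)")
  } else w("(empty: synteny stage not run)")
  w("", "## Dating summary (My)")
  if (!is.null(res$dating_summary)) {
    d <- res$dating_summary
    w(paste(colnames(d), collapse = "\t"))
    for (i in seq_len(nrow(d))) {
      w(paste(round(unlist(d[i, -1]), 2), collapse = "\t") |>
          (\(x) paste(d$node[i], x, sep = "\t"))())
    }
    w("")
    for (locus in names(res$min_ages)) {
      w(sprintf("Minimum insertion age (%s, carrier MRCA): %.1f My",
                locus, res$min_ages[[locus]]$age))
    }
  } else w("", "(not run)")
  w("", "## Neutrality test")
  if (!is.null(res$neutrality)) {
    k <- ks_report(res)
    w(paste(colnames(k), collapse = "\t"))
    for (i in seq_len(nrow(k))) {
      w(paste(unlist(k[i, ]), collapse = "\t"))
    }
  } else w("not run")
  invisible(path)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline_result: stages",
      paste(names(x$reports), collapse = " -> "), "\n")
  invisible(x)
}
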