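# End-to-end runner: simulated (or user-supplied) dataset -> ancestry
# summaries, assortment test, timing fits with and without rho, sex-bias
# grid, ROH and IBD reports. Every stochastic stage derives its seed
# deterministically from the master seed and the stage name, so a rerun
# with the same config is identical.

.pipeline_defaults <- function() {
  list(
    seed = 1L,
    stages = c("ancestry", "assort", "lad", "timing", "sexbias", "roh", "ibd"),
    simulate = list(G = 20, N = 500, rho = 0.4, map_scale = 0.5,
                    s1f = 0.10, s1m = 0, s2f = 0, s2m = 0.05,
                    population = "demo"),
    inputs = NULL,                 # list(tracts=, samples=, map=) to skip simulation
    lad = list(window_mb = 10, overlap_mb = 1, step_mb = NULL),
    timing = list(g_min = 5, g_max = 25, m = c(0, 0.01), h0 = NULL,
                  rho_source = "assort", rho_fixed = NULL),
    assort = list(B = 1000),
    sexbias = list(G = NULL, increment = 0.02, keep = 0.001),
    roh = list(scheme = "fixed", boundary_gen = 20),
    ibd = list(min_cm = 5, edge_cm = 150, top_quantile = NULL,
               n_samples = 100)
  )
}

#' Pipeline configuration
#'
#' Builds a validated configuration for [run_pipeline()]. Unknown keys (top
#' level or within a block) are errors, not warnings. The default
#' configuration simulates a demonstration population: N = 500 diploids for
#' G = 20 generations on a half-scale 22-autosome + X map, with
#' female-biased source-1 and male-biased source-2 constant contributions
#' (s1f = 0.10, s2m = 0.05) and spousal ancestry correlation rho = 0.4.
#'
#' @param ... named overrides of the defaults; blocks (`simulate`, `lad`,
#'   `timing`, `assort`, `sexbias`, `roh`, `ibd`) are merged key-wise.
#'   Supply `inputs = list(tracts =, samples =, map =)` (objects or file
#'   paths) to analyze existing data instead of simulating; ROH/IBD stages
#'   then require `inputs$roh` / `inputs$ibd` segment tables.
#' @param seed master seed; per-stage seeds derive from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(..., seed = 1) {
  cfg <- .pipeline_defaults()
  cfg$seed <- as.integer(seed)
  dots <- list(...)
  if (length(dots) && is.null(names(dots))) stop("overrides must be named")
  for (nm in names(dots)) {
    if (!nm %in% names(cfg)) stop(sprintf("unknown config key: '%s'", nm))
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]]) && nm != "inputs") {
      for (k in names(dots[[nm]])) {
        if (!k %in% names(cfg[[nm]])) {
          stop(sprintf("unknown config key: '%s$%s'", nm, k))
        }
        cfg[[nm]][[k]] <- dots[[nm]][[k]]
      }
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  bad <- setdiff(cfg$stages,
                 c("ancestry", "assort", "lad", "timing", "sexbias", "roh", "ibd"))
  if (length(bad)) {
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")))
  }
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order
#' (simulate -> ancestry -> assort -> lad -> timing -> sexbias -> roh ->
#' ibd), skipping any stage not listed in `config$stages`. The timing stage
#' fits the LAD decay twice per migration rate: once under random mating
#' (rho = 0) and once at the assortment stage's median R (the empirical
#' plumbing: the attenuated parental-correlation estimate feeds the LAD
#' fit), unless `timing$rho_source = "fixed"`.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_bundle` list with one element per executed stage plus
#'   `manifest` (package version, seeds, parameter echo). Reruns with the
#'   same config are identical.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  master <- config$seed
  bundle <- list()
  seeds <- list()

  # --- data: simulate or load ------------------------------------------------
  if (!length(config$stages)) {
    # all stage toggles off: manifest only
    bundle$manifest <- list(
      package = "admixisle",
      version = as.character(packageVersion("admixisle")),
      master_seed = master, stage_seeds = seeds, config = unclass(config))
    class(bundle) <- "pipeline_bundle"
    return(bundle)
  }
  if (is.null(config$inputs)) {
    seeds$simulate <- stage_seed(master, "simulate")
    sc <- config$simulate
    map <- example_map(scale = sc$map_scale)
    sched <- contribution_schedule(sc$G, sc$s1f, sc$s1m, sc$s2f, sc$s2m)
    sim <- simulate_admixture(sim_config(
      map, G = sc$G, N = sc$N, schedule = sched, rho = sc$rho,
      seed = seeds$simulate, population = sc$population))
    tracts <- sim$tracts
    samples <- sim$samples
    bundle$simulate <- sim
  } else {
    inp <- config$inputs
    map <- inp$map
    stopifnot(inherits(map, "genetic_map"))
    tracts <- if (is.character(inp$tracts)) read_tracts(inp$tracts, map) else inp$tracts
    samples <- if (is.character(inp$samples)) read_samples(inp$samples) else inp$samples
    sim <- NULL
  }

  run <- function(st) st %in% config$stages

  # --- ancestry --------------------------------------------------------------
  if (run("ancestry")) {
    anc_auto <- global_ancestry(tracts, map, "autosomes")
    anc_x <- if (any(map$is_X)) global_ancestry(tracts, map, "X") else NULL
    st <- list(auto = anc_auto, x = anc_x,
               by_population = population_summary(anc_auto, samples))
    if (!is.null(anc_x) && nrow(anc_x) >= 6) {
      st$x_vs_auto <- tryCatch(x_vs_auto_test(anc_auto, anc_x),
                               error = function(e) e$message)
    }
    bundle$ancestry <- st
  }

  # --- assortment ------------------------------------------------------------
  if (run("assort")) {
    seeds$assort <- stage_seed(master, "assort")
    bundle$assort <- assortment_test(tracts, map, B = config$assort$B,
                                     seed = seeds$assort)
  }

  # --- LAD windows -----------------------------------------------------------
  if (run("lad")) {
    lcfg <- config$lad
    bundle$lad <- lad_windows(tracts, map, window_mb = lcfg$window_mb,
                              overlap_mb = lcfg$overlap_mb,
                              step_mb = lcfg$step_mb)
  }

  # --- timing fits -----------------------------------------------------------
  if (run("timing")) {
    if (is.null(bundle$lad)) stop("timing stage requires the lad stage")
    tcfg <- config$timing
    h0 <- tcfg$h0 %||% mean(bundle$ancestry$auto$prop %||%
                              global_ancestry(tracts, map, "autosomes")$prop)
    rhos <- c(random_mating = 0)
    if (identical(tcfg$rho_source, "assort")) {
      if (is.null(bundle$assort)) stop("timing rho_source 'assort' requires the assort stage")
      rhos <- c(rhos, assort_estimate = max(0, bundle$assort$median_r))
    } else if (!is.null(tcfg$rho_fixed)) {
      rhos <- c(rhos, fixed = tcfg$rho_fixed)
    }
    fits <- list()
    tab <- list()
    for (rn in names(rhos)) {
      for (mm in tcfg$m) {
        f <- suppressWarnings(
          fit_generations(bundle$lad, rho = rhos[[rn]], m = mm, h0 = h0,
                          g_min = tcfg$g_min, g_max = tcfg$g_max))
        fits[[paste0(rn, "_m", mm)]] <- f
        tab[[length(tab) + 1L]] <- data.frame(
          rho_label = rn, rho = rhos[[rn]], m = mm, h0 = h0,
          best_g = f$best_g, stringsAsFactors = FALSE)
      }
    }
    bundle$timing <- list(table = do.call(rbind, tab), fits = fits)
  }

  # --- sex bias --------------------------------------------------------------
  if (run("sexbias")) {
    if (!any(map$is_X)) stop("sexbias stage requires an X chromosome in the map")
    scfg <- config$sexbias
    Gs <- scfg$G %||% (if (!is.null(config$inputs)) 20L else config$simulate$G)
    anc_auto <- bundle$ancestry$auto %||% global_ancestry(tracts, map, "autosomes")
    # dosage-weighted pooled X mean: total S1 X length over total X length
    xtr <- tracts[tracts$chrom %in% map$chrom[map$is_X], , drop = FALSE]
    cm <- interval_cm(map, xtr$chrom, xtr$start, xtr$end)
    obs_x <- sum(cm[xtr$ancestry == "S1"]) / sum(cm)
    pf <- mean(samples$sex == "F")
    bundle$sexbias <- sexbias_grid(mean(anc_auto$prop), obs_x, pf = pf,
                                   G = Gs, increment = scfg$increment,
                                   keep = scfg$keep)
  }

  # --- ROH -------------------------------------------------------------------
  if (run("roh")) {
    rcfg <- config$roh
    roh <- if (!is.null(config$inputs)) {
      if (is.null(config$inputs$roh)) stop("roh stage requires inputs$roh")
      config$inputs$roh
    } else {
      autozygosity_truth(sim$founder_segments, map)
    }
    cls <- if (identical(rcfg$scheme, "gmm3")) {
      classify_roh(roh, "gmm3")
    } else {
      classify_roh(roh, "fixed",
                   boundary_mb = boundary_from_generations(rcfg$boundary_gen))
    }
    anc_auto <- bundle$ancestry$auto %||% global_ancestry(tracts, map, "autosomes")
    bundle$roh <- list(
      classification = cls,
      summaries = roh_summaries(cls, ancestry = anc_auto, samples = samples),
      switches = ancestry_switches_in_roh(cls, tracts))
  }

  # --- IBD -------------------------------------------------------------------
  if (run("ibd")) {
    icfg <- config$ibd
    seeds$ibd <- stage_seed(master, "ibd")
    ibd <- if (!is.null(config$inputs)) {
      if (is.null(config$inputs$ibd)) stop("ibd stage requires inputs$ibd")
      config$inputs$ibd
    } else {
      with_seed(seeds$ibd, {
        ids <- samples$sample
        if (length(ids) > icfg$n_samples) {
          ids <- sort(sample(ids, icfg$n_samples))
        }
        seg <- sim$founder_segments
        ibd_truth(seg[seg$sample %in% ids, , drop = FALSE], map,
                  max_pairs = choose(icfg$n_samples, 2))
      })
    }
    totals <- pairwise_ibd_totals(ibd, min_cm = icfg$min_cm)
    bundle$ibd <- list(
      totals = totals,
      network = ibd_network(totals, edge_cm = icfg$edge_cm,
                            top_quantile = icfg$top_quantile),
      kinship = kinship_proxy(ibd, map))
  }

  bundle$manifest <- list(
    package = "admixisle",
    version = as.character(packageVersion("admixisle")),
    master_seed = master,
    stage_seeds = seeds,
    config = unclass(config))
  class(bundle) <- "pipeline_bundle"
  bundle
}

#' Human-readable summary of a pipeline bundle
#'
#' One section per executed stage, numbers only; missing stages are noted
#' and not fatal.
#'
#' @param bundle a [run_pipeline()] result.
#' @return character vector of report lines (also printed).
#' @export
make_report <- function(bundle) {
  stopifnot(inherits(bundle, "pipeline_bundle"))
  ln <- character(0)
  add <- function(...) ln <<- c(ln, sprintf(...))
  add("== admixisle pipeline report ==")
  add("master seed: %d", bundle$manifest$master_seed)
  if (!is.null(bundle$ancestry)) {
    a <- bundle$ancestry
    add("-- ancestry --")
    add("mean autosomal S1 ancestry: %.4f", mean(a$auto$prop))
    if (!is.null(a$x)) add("mean X S1 ancestry: %.4f", mean(a$x$prop))
    if (is.list(a$x_vs_auto)) {
      add("X vs autosomes Wilcoxon signed-rank: V = %g, p = %.3g",
          a$x_vs_auto$statistic, a$x_vs_auto$p_value)
    }
  } else add("-- ancestry: not run --")
  if (!is.null(bundle$assort)) {
    add("-- assortative mating --")
    add("median parental-ancestry R: %.4f (permutation p = %.4g, B = %d)",
        bundle$assort$median_r, bundle$assort$p, bundle$assort$B)
  } else add("-- assort: not run --")
  if (!is.null(bundle$lad)) {
    add("-- LAD --")
    add("%d windows, mean LAD = %.4f", nrow(bundle$lad),
        attr(bundle$lad, "mean_lad"))
  }
  if (!is.null(bundle$timing)) {
    add("-- admixture timing --")
    t <- bundle$timing$table
    for (i in seq_len(nrow(t))) {
      add("rho = %.3f (%s), m = %.2f: best g = %d",
          t$rho[i], t$rho_label[i], t$m[i], t$best_g[i])
    }
  }
  if (!is.null(bundle$sexbias)) {
    s <- bundle$sexbias
    add("-- sex bias --")
    add("observed H_auto = %.4f, H_X = %.4f", s$settings$obs_auto,
        s$settings$obs_x)
    add("median retained f1 = %.3f, f2 = %.3f", s$median_f1, s$median_f2)
  }
  if (!is.null(bundle$roh)) {
    r <- bundle$roh
    add("-- ROH --")
    add("%d segments; boundaries (bp): %s", nrow(r$classification$segments),
        paste(format(round(r$classification$boundaries_bp)), collapse = ", "))
    if (!is.null(r$summaries$correlations)) {
      cr <- r$summaries$correlations
      for (i in seq_len(nrow(cr))) {
        add("cor(%s ROH, S1 ancestry) = %.3f (p = %.3g)",
            cr$class[i], cr$r[i], cr$p[i])
      }
    }
    for (i in seq_len(nrow(r$switches$by_class))) {
      b <- r$switches$by_class[i, ]
      add("class %s: %.2f%% with >= 1 ancestry switch; %.3f switches/Mb",
          b$class, 100 * b$frac_with_switch, b$mean_per_mb)
    }
  }
  if (!is.null(bundle$ibd)) {
    add("-- IBD --")
    add("%d pairs with shared IBD; %d network edges; mean kinship %.4f",
        nrow(bundle$ibd$totals), nrow(bundle$ibd$network),
        mean(bundle$ibd$kinship$kinship))
  }
  cat(paste(ln, collapse = "\n"), "\n")
  invisible(ln)
}
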