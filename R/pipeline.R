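#' Run configuration for the full analysis pipeline
#'
#' @param dataset_csv path to the dataset CSV (see [load_dataset()]).
#' @param newick path to the Newick tree.
#' @param responses tumour types to model (default all k_* columns found).
#' @param structure_families families to fit and compare (default OU and
#'   LAMBDA).
#' @param mcmc an `mcmc_config` (its seed is overridden by `master_seed`).
#' @param out_dir output directory, created if needed.
#' @param master_seed integer seed recorded in every output.
#' @param resample run the necropsy-shuffling study per response (default
#'   FALSE).
#' @param n_replicates resampling replicates (default 50).
#' @return a `run_config` list.
#' @export
run_config <- function(dataset_csv, newick, responses = NULL,
                       structure_families = c("OU", "LAMBDA"),
                       mcmc = mcmc_config(), out_dir = "phyloprev-out",
                       master_seed = 1L, resample = FALSE,
                       n_replicates = 50L) {
  if (!file.exists(dataset_csv)) stop("dataset CSV not found: ", dataset_csv)
  if (!file.exists(newick)) stop("Newick file not found: ", newick)
  structure(list(dataset_csv = dataset_csv, newick = newick,
                 responses = responses,
                 structure_families = structure_families, mcmc = mcmc,
                 out_dir = out_dir, master_seed = as.integer(master_seed),
                 resample = resample, n_replicates = as.integer(n_replicates)),
            class = "run_config")
}

provenance <- function(config) {
  list(package = "phyloprev",
       version = as.character(utils::packageVersion("phyloprev")),
       master_seed = config$master_seed,
       dataset_csv = config$dataset_csv, newick = config$newick)
}

#' Run the full reanalysis pipeline
#'
#' Loads the dataset and tree, fits the standard model grid (mass-only,
#' longevity-only, both, interaction) per response and structure family,
#' applies the convergence gate (failing fits are re-run once with 4x
#' iterations), computes information criteria, OU-vs-lambda comparisons,
#' odds-ratio summaries and marginal curves, and optionally the resampling
#' study. Everything is written under `config$out_dir` with the master seed
#' and provenance echoed; per-cell errors go to a failure manifest instead of
#' aborting the run.
#'
#' @param config a `run_config`.
#' @return (invisibly) a list with all in-memory results.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tree <- read_newick(config$newick, normalize_depth = TRUE)
  dataset <- load_dataset(config$dataset_csv, tree)
  responses <- config$responses
  if (is.null(responses)) responses <- names(dataset$counts)
  mcmc <- mcmc_config(config$mcmc$iterations, config$mcmc$burn_in,
                      config$mcmc$thin, config$mcmc$chains,
                      seed = config$master_seed)
  failures <- list()
  fits <- list()
  for (fam in config$structure_families) {
    f <- fit_all_specs(dataset, tree, responses, mcmc, structure_family = fam)
    fits <- c(fits, f)
  }

  summaries <- list()
  effects <- list()
  comparisons <- list()
  for (key in names(fits)) {
    fit <- fits[[key]]
    if (inherits(fit, "fit_error")) {
      failures[[key]] <- fit$error
      next
    }
    conv <- convergence_report(fit)
    if (!conv$pass) { # one retry with 4x iterations
      m2 <- mcmc_config(mcmc$iterations * 4L, mcmc$burn_in * 4L, mcmc$thin,
                        mcmc$chains, seed = config$master_seed)
      fit2 <- tryCatch(sample_posterior(dataset, tree, fit$spec, m2),
                       error = function(e) NULL)
      if (!is.null(fit2)) {
        fit <- fit2
        fits[[key]] <- fit
        conv <- convergence_report(fit)
      }
    }
    ic <- ic_report(fit)
    eff <- lapply(setdiff(fit$parameters,
                          c("sigma_phylo", "alpha", "lambda", "(Intercept)")),
                  function(cf) odds_ratio_summary(fit, cf))
    names(eff) <- vapply(eff, `[[`, "", "coefficient")
    curves <- lapply(fit$spec$predictors, function(p)
      marginal_effect_curve(fit, predictor = p))
    names(curves) <- fit$spec$predictors
    for (p in names(curves))
      write_curve_csv(curves[[p]], file.path(config$out_dir,
                                             paste0("curve_", key, "_", p, ".csv")))
    summaries[[key]] <- list(
      spec = unclass(fit$spec),
      convergence = list(pass = conv$pass, table = conv$table),
      ic = list(waic = ic$waic, p_waic = ic$p_waic, looic = ic$looic,
                n_high_k = ic$n_high_k),
      effects = lapply(eff, function(e) list(
        coefficient = e$coefficient, or = e$or,
        or_q2.5 = e$or_q[["q2.5"]], or_q97.5 = e$or_q[["q97.5"]],
        significant = e$significant, direction = e$direction)))
    effects[[key]] <- eff
  }

  if (all(c("OU", "LAMBDA") %in% config$structure_families)) {
    ou_keys <- grep("\\.OU$", names(fits), value = TRUE)
    for (ko in ou_keys) {
      kl <- sub("\\.OU$", ".LAMBDA", ko)
      if (kl %in% names(fits) && inherits(fits[[ko]], "posterior_fit") &&
          inherits(fits[[kl]], "posterior_fit")) {
        comparisons[[sub("\\.OU$", "", ko)]] <-
          compare_structures(fits[[ko]], fits[[kl]])
      }
    }
    if (length(comparisons)) {
      comp_df <- do.call(rbind, lapply(names(comparisons), function(nm) {
        cmp <- comparisons[[nm]]
        data.frame(model = nm, preferred = cmp$preferred,
                   delta_waic = cmp$delta_waic, delta_looic = cmp$delta_looic,
                   indistinguishable = cmp$indistinguishable)
      }))
      write.csv(comp_df, file.path(config$out_dir, "structure_comparison.csv"),
                row.names = FALSE)
    }
  }

  resampling <- NULL
  if (config$resample) {
    resampling <- lapply(responses, function(resp) {
      spec <- model_spec(resp, structure_family = config$structure_families[1])
      resampling_study(dataset, tree, spec, n_replicates = config$n_replicates,
                       master_seed = config$master_seed)
    })
    names(resampling) <- responses
    for (resp in responses) {
      write.csv(resampling[[resp]]$replicates,
                file.path(config$out_dir, paste0("resampling_", resp, ".csv")),
                row.names = FALSE)
    }
  }

  out <- list(provenance = provenance(config),
              n_models = length(fits),
              summaries = summaries, comparisons = lapply(comparisons, unclass),
              failures = failures)
  jsonlite::write_json(out, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  if (length(failures))
    jsonlite::write_json(failures, file.path(config$out_dir, "failures.json"),
                         auto_unbox = TRUE)
  message(length(fits), " models fitted (no multiplicity correction applied)")
  invisible(list(fits = fits, summaries = summaries, comparisons = comparisons,
                 resampling = resampling, failures = failures,
                 dataset = dataset, tree = tree))
}

#' Command-line entry point
#'
#' Subcommands: `fit` (full pipeline), `compare` (OU vs lambda only),
#' `resample`, `simulate` (write a synthetic dataset CSV + Newick + truth
#' JSON), and `ci-width` (expected Jeffreys-interval width vs n). Invoke via
#' `Rscript -e 'phyloprev::prevalence_cli()' <subcommand> [options]` or the
#' installed `exec/phyloprev` script.
#'
#' @param args character vector of CLI arguments (default:
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status (invisibly).
#' @export
prevalence_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L) {
    cat("usage: phyloprev <fit|compare|resample|simulate|ci-width> [options]\n")
    return(invisible(1L))
  }
  cmd <- args[1]
  rest <- args[-1]
  opt_common <- list(
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character", default = "phyloprev-out"))
  if (cmd %in% c("fit", "compare", "resample")) {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = c(
      opt_common,
      list(optparse::make_option("--data", type = "character"),
           optparse::make_option("--tree", type = "character"),
           optparse::make_option("--response", type = "character", default = NULL),
           optparse::make_option("--iterations", type = "integer", default = 5000L),
           optparse::make_option("--burn-in", type = "integer", default = 2000L),
           optparse::make_option("--thin", type = "integer", default = 5L),
           optparse::make_option("--chains", type = "integer", default = 4L),
           optparse::make_option("--replicates", type = "integer", default = 50L),
           optparse::make_option("--family", type = "character", default = "OU")))),
      args = rest)
    mc <- mcmc_config(opts$iterations, opts$`burn-in`, opts$thin, opts$chains,
                      seed = opts$seed)
    responses <- if (is.null(opts$response)) NULL else
      strsplit(opts$response, ",")[[1]]
    fams <- if (cmd == "compare") c("OU", "LAMBDA") else
      strsplit(opts$family, ",")[[1]]
    cfg <- run_config(opts$data, opts$tree, responses = responses,
                      structure_families = fams, mcmc = mc,
                      out_dir = opts$out, master_seed = opts$seed,
                      resample = cmd == "resample",
                      n_replicates = opts$replicates)
    run_full_analysis(cfg)
  } else if (cmd == "simulate") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = c(
      opt_common,
      list(optparse::make_option("--species", type = "integer", default = 100L),
           optparse::make_option("--beta-mass", type = "double", default = 0),
           optparse::make_option("--beta-longevity", type = "double", default = 0),
           optparse::make_option("--sigma", type = "double", default = 0.5)))),
      args = rest)
    cfg <- simulation_config(n_species = opts$species,
                             beta_mass = opts$`beta-mass`,
                             beta_longevity = opts$`beta-longevity`,
                             sigma_phylo = opts$sigma, seed = opts$seed)
    sim <- simulate_dataset(cfg)
    dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
    write_dataset_csv(sim$dataset, file.path(opts$out, "dataset.csv"))
    ape::write.tree(sim$tree, file.path(opts$out, "tree.nwk"))
    jsonlite::write_json(sim$truth[setdiff(names(sim$truth), c("u", "p"))],
                         file.path(opts$out, "truth.json"), auto_unbox = TRUE)
    message("synthetic dataset written to ", opts$out)
  } else if (cmd == "ci-width") {
    opts <- optparse::parse_args(optparse::OptionParser(option_list = c(
      opt_common,
      list(optparse::make_option("--prevalence", type = "double", default = 0.1),
           optparse::make_option("--n-grid", type = "character",
                                 default = "10,25,50,100,400")))),
      args = rest)
    grid <- as.integer(strsplit(opts$`n-grid`, ",")[[1]])
    curve <- ci_width_curve(opts$prevalence, grid)
    dir.create(opts$out, showWarnings = FALSE, recursive = TRUE)
    write.csv(curve, file.path(opts$out, "ci_width.csv"), row.names = FALSE)
    print(curve)
  } else {
    stop("unknown subcommand: ", cmd)
  }
  invisible(0L)
}
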