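# seed scheme: every pipeline stage s (1 = simulate, 2 = fit domain 1, ...)
# draws its own seed from the master so partial re-runs are reproducible
.derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) + 1009 * offset) %% 2147483647L)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (optional) -> validate -> centre -> design -> fit ->
#' report for every testing domain, plus any sensitivity variants, writing
#' all artifacts under `config$out_dir` and returning a manifest of produced
#' files with content hashes. Runs are deterministic given identical config
#' and master seed.
#'
#' `config` is a list (or path to a YAML file with the same structure):
#' \describe{
#'   \item{simulation}{optional named list of [sim_config()] arguments (use
#'     `truth` as a list of [sim_truth()] arguments); if absent, `inputs`
#'     must give paths `observations`, `profiles`, `reference`.}
#'   \item{domains}{domains to analyse; default all present.}
#'   \item{event_year}{interruption year (default 2014).}
#'   \item{mcmc}{named list of [mcmc_config()] arguments.}
#'   \item{priors}{named list of [prior_spec()] arguments (SD priors given
#'     as `list(mean=, sd=)` or a fixed number).}
#'   \item{variants}{named list of [sensitivity_variant()] argument lists.}
#'   \item{out_dir}{output directory.}
#'   \item{seed}{master seed.}
#' }
#'
#' @param config List or YAML path as described above.
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$out_dir)) stop("config$out_dir is required")
  if (is.null(config$seed)) stop("config$seed is required")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  event_year <- if (is.null(config$event_year)) 2014 else config$event_year
  master <- as.integer(config$seed)

  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(...) cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...,
                            "\n", sep = "", file = log_path, append = TRUE)
  logf("pipeline start, master seed ", master)

  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    if (!is.null(sim_args$truth) && !inherits(sim_args$truth, "sim_truth"))
      sim_args$truth <- do.call(sim_truth, as.list(sim_args$truth))
    sim_args$seed <- .derive_seed(master, 1L)
    study <- do.call(sim_config, sim_args)
    study <- generate_study(study)
    logf("simulated study: ", nrow(study$observations), " observations")
    write_study(study, out_dir)
    observations <- study$observations
    profiles <- study$profiles
    reference <- study$reference
  } else if (!is.null(config$inputs)) {
    observations <- read_observations(config$inputs$observations)
    profiles <- read_profiles(config$inputs$profiles)
    reference <- read_reference_means(config$inputs$reference)
    logf("loaded study: ", nrow(observations), " observations")
  } else stop("config needs either `simulation` or `inputs`")

  val <- validate_tables(observations, profiles, drop = TRUE)
  logf("validation: ", sum(val$report$n_violations), " violations (dropped)")
  write.csv(val$report, file.path(out_dir, "validation_report.csv"),
            row.names = FALSE)
  observations <- val$observations
  profiles <- val$profiles
  if (!all(observations$centred))
    observations <- center_scores(observations, reference)

  domains <- config$domains
  if (is.null(domains)) domains <- sort(unique(observations$domain))
  if (length(domains) == 0) stop("config: domain list is empty")

  priors <- if (is.null(config$priors)) prior_spec() else {
    pa <- config$priors
    for (nm in c("sigma_cohort", "sigma_school", "sigma_e"))
      if (!is.null(pa[[nm]]) && is.list(pa[[nm]]))
        pa[[nm]] <- do.call(tn_prior, pa[[nm]])
    do.call(prior_spec, pa)
  }
  mcmc_args <- if (is.null(config$mcmc)) list() else config$mcmc

  fits <- list()
  for (d in seq_along(domains)) {
    dom <- domains[d]
    logf("fitting domain ", dom)
    design <- build_design(observations, profiles, domain = dom,
                           event_year = event_year)
    mcmc <- do.call(mcmc_config,
                    modifyList(mcmc_args,
                               list(seed = .derive_seed(master, 1L + d))))
    fit <- fit_model(design, priors, mcmc)
    fits[[dom]] <- list(fit = fit, design = design)

    tab <- coef_table(fit)
    write.csv(as.data.frame(tab),
              file.path(out_dir, paste0("coefficients_", dom, ".csv")),
              row.names = FALSE)
    margins <- predicted_margins(fit)
    write.csv(margins, file.path(out_dir, paste0("margins_", dom, ".csv")),
              row.names = FALSE)
    jsonlite::write_json(
      list(domain = dom, seed = mcmc$seed,
           diagnostics = fit$diagnostics, divergences = fit$divergences),
      file.path(out_dir, paste0("diagnostics_", dom, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")

    if (!is.null(config$variants) && length(config$variants) > 0) {
      tabs <- list(base = tab)
      for (vn in names(config$variants)) {
        v <- config$variants[[vn]]
        if (!inherits(v, "sensitivity_variant")) {
          if (!is.null(v$prior_override) && is.list(v$prior_override))
            v$prior_override <- do.call(prior_spec, v$prior_override)
          v <- do.call(sensitivity_variant, c(list(name = vn), v))
        }
        vt <- run_variant(design, priors, v, mcmc)
        attr(vt, "fit") <- NULL
        tabs[[vn]] <- vt
        write.csv(as.data.frame(vt),
                  file.path(out_dir,
                            paste0("coefficients_", dom, "_", vn, ".csv")),
                  row.names = FALSE)
      }
      write.csv(compare_variants(tabs),
                file.path(out_dir, paste0("comparison_", dom, ".csv")),
                row.names = FALSE)
    }
  }

  all_margins <- do.call(rbind, lapply(fits, function(f)
    predicted_margins(f$fit)))
  plot_path <- file.path(out_dir, "trends.png")
  tryCatch({
    p <- plot_trends(all_margins, event_year = event_year)
    ggplot2::ggsave(plot_path, p, width = 9,
                    height = 3 * ceiling(length(domains) / 2), dpi = 120)
    logf("wrote trends plot")
  }, error = function(e) logf("trends plot skipped: ", conditionMessage(e)))

  files <- setdiff(list.files(out_dir, recursive = TRUE),
                   c("manifest.json", "pipeline.log"))
  manifest <- list(
    seed = master,
    config_hash = .hash_object(config[setdiff(names(config), "out_dir")]),
    domains = domains,
    files = data.frame(
      path = files,
      md5 = as.character(tools::md5sum(file.path(out_dir, files))),
      stringsAsFactors = FALSE, row.names = NULL))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  logf("pipeline done: ", length(files), " artifacts")
  invisible(manifest)
}

.hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(x, tmp)
  as.character(tools::md5sum(tmp))
}

#' Plot predicted centred-score trends
#'
#' Line plot of predicted margins with credible-interval error bars, one
#' line per exposure group, a vertical marker at the event year, facetted
#' by domain when several are present.
#'
#' @param margins A margins table from [predicted_margins()] (rows for all
#'   requested groups and years).
#' @param event_year Year to mark; omit for no marker.
#' @return A ggplot object.
#' @export
plot_trends <- function(margins, event_year = NULL) {
  needed <- c("year", "exposure_group", "mean", "lower", "upper")
  miss <- setdiff(needed, colnames(margins))
  if (length(miss) > 0)
    stop("margins table is missing column(s): ", paste(miss, collapse = ", "))
  groups <- unique(margins$exposure_group)
  counts <- table(margins$exposure_group,
                  if (is.null(margins$domain)) "all" else margins$domain)
  if (any(counts == 0)) stop("margins table has empty group x domain cells")
  p <- ggplot2::ggplot(margins,
                       ggplot2::aes(x = .data$year, y = .data$mean,
                                    colour = .data$exposure_group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lower,
                                        ymax = .data$upper), width = 0.2) +
    ggplot2::labs(x = "Year", y = "Predicted centred score",
                  colour = "Exposure") +
    ggplot2::theme_minimal()
  if (!is.null(event_year))
    p <- p + ggplot2::geom_vline(xintercept = event_year,
                                 linetype = "dashed", colour = "grey40")
  if (!is.null(margins$domain) && length(unique(margins$domain)) > 1)
    p <- p + ggplot2::facet_wrap(~domain)
  p
}
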