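#' Pipeline configuration
#'
#' Bundles every knob of an end-to-end run: seeds for each random stage,
#' the registry layout, generator parameters, sampler settings and output
#' location. Configurations round-trip through JSON unchanged.
#'
#' @param out_dir Output directory for the run.
#' @param seed Master integer seed; stage seeds derive from it and are
#'   recorded in the manifest. Required.
#' @param registry A [registry_config()].
#' @param wear A [wear_params()].
#' @param n_pix Surface grid size for the demo surface stage.
#' @param demo_surfaces Number of surfaces per manufacturing state to carry
#'   through preprocessing and parameter extraction (0 disables the stage).
#' @param models Character vector of models to fit.
#' @param chains,warmup,draws Sampler settings.
#' @param n_fit Optional row cap for the model-fitting stage (rows are
#'   subsampled deterministically); `NULL` fits the full table.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed, registry = registry_config(),
                            wear = wear_params(), n_pix = 128L,
                            demo_surfaces = 1L,
                            models = c("M0", "M1", "M2", "M3"),
                            chains = 2L, warmup = 500L, draws = 500L,
                            n_fit = NULL) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("config missing a seed: field 'seed' is required")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 registry = registry, wear = wear, n_pix = as.integer(n_pix),
                 demo_surfaces = as.integer(demo_surfaces), models = models,
                 chains = chains, warmup = warmup, draws = draws,
                 n_fit = n_fit),
            class = "pipeline_config")
}

log_line <- function(stage, ...) {
  kv <- paste(vapply(list(...), as.character, character(1)),
              collapse = " ")
  message(sprintf("%s stage=%s %s",
                  format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), stage, kv))
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> (demo surfaces -> preprocess -> parameters) ->
#' fit(M0..M3) -> WAIC/ICC/goodness-of-fit -> report, writing all artifacts
#' and a manifest (seeds, file checksums, stage status) under
#' `config$out_dir`. Stage errors are recorded in the manifest and
#' downstream stages are skipped.
#'
#' @param config A [pipeline_config()].
#' @return The manifest list, invisibly; artifacts are on disk.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stop("expected a pipeline_config")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("osteotex")),
                   r_version = R.version.string,
                   seed = config$seed, stages = list(), files = list())
  failed <- FALSE

  run_stage <- function(name, fun) {
    if (failed) {
      manifest$stages[[name]] <<- list(status = "skipped")
      return(NULL)
    }
    out <- tryCatch(fun(), error = function(e) e)
    if (inherits(out, "error")) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(out))
      failed <<- TRUE
      log_line(name, "status=error", conditionMessage(out))
      NULL
    } else {
      manifest$stages[[name]] <<- list(status = "ok")
      out
    }
  }
  record_file <- function(path) {
    manifest$files[[basename(path)]] <<-
      unname(tools::md5sum(path))
  }

  tab <- run_stage("simulate", function() {
    reg <- build_registry(config$registry)
    tab <- simulate_observation_table(reg, config$wear, seed = config$seed)
    f <- file.path(config$out_dir, "observations.csv")
    utils::write.csv(tab, f, row.names = FALSE)
    record_file(f)
    log_line("simulate", paste0("rows=", nrow(tab)))
    tab
  })

  run_stage("surfaces", function() {
    if (config$demo_surfaces < 1L) return(invisible(NULL))
    rows <- list()
    for (st in c("UW", "GS", "SF")) {
      for (r in seq_len(config$demo_surfaces)) {
        sd0 <- config$seed + 100 * r + match(st, c("UW", "GS", "SF"))
        hm <- simulate_base_surface(st, seed = sd0, n_pix = config$n_pix,
                                    wp = config$wear)
        pp <- preprocess_pipeline(hm, preprocess_config())
        pars <- compute_all_params(pp)
        rows[[length(rows) + 1L]] <-
          data.frame(state = st, replicate = r, Sa_um = pars["Sa"],
                     Sal_um = pars["Sal"], Spc_inv_um = pars["Spc"],
                     Smr1_pct = pars["Smr1"], row.names = NULL)
      }
    }
    f <- file.path(config$out_dir, "surface_params.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    record_file(f)
    log_line("surfaces", paste0("n=", length(rows)))
  })

  fits <- run_stage("fit", function() {
    stopifnot(!is.null(tab))
    ft <- tab
    if (!is.null(config$n_fit) && nrow(ft) > config$n_fit)
      ft <- ft[seq_len(config$n_fit), ]
    fits <- list()
    for (m in config$models) {
      fits[[m]] <- fit_mcmc(table = ft, model_id = m, chains = config$chains,
                            warmup = config$warmup, draws = config$draws,
                            seed = config$seed)
      log_line("fit", paste0("model=", m),
               paste0("max_rhat=", round(fits[[m]]$max_rhat, 3)),
               paste0("converged=", fits[[m]]$converged))
    }
    fits
  })

  run_stage("compare", function() {
    stopifnot(!is.null(fits))
    wt <- waic_table(fits)
    f <- file.path(config$out_dir, "waic.csv")
    utils::write.csv(wt, f, row.names = FALSE)
    record_file(f)
    best <- fits[[which.min(wt$waic)]]
    icc <- compute_icc(best)
    f2 <- file.path(config$out_dir, "icc.csv")
    utils::write.csv(rbind(cbind(factor = "lot", icc$lot),
                           cbind(factor = "specimen", icc$spec)),
                     f2, row.names = FALSE)
    record_file(f2)
    gof <- mahalanobis_gof(best)
    f3 <- file.path(config$out_dir, "gof_qq.csv")
    utils::write.csv(gof, f3, row.names = FALSE)
    record_file(f3)
    log_line("compare", paste0("best=", wt$model[which.min(wt$waic)]))
  })

  run_stage("report", function() {
    stopifnot(!is.null(fits))
    render_report(config$out_dir, fits)
  })

  mf <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Render report figures and tables from fitted models
#'
#' Writes the standard result set: pairwise posterior-ellipse panels at
#' time 0 by manufacturing state, predicted mean trajectories by state and
#' material, the WAIC ladder, ICC table, and the Mahalanobis QQ plot. Every
#' figure is written next to the CSV of its underlying numbers; axes of
#' log-scale figures are labelled in original measurement units.
#'
#' @param out_dir Output directory.
#' @param fits Named list of `texture_fit` objects; the most complex
#'   converged fit drives the figures.
#' @return Invisibly, the vector of files written.
#' @export
render_report <- function(out_dir, fits) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  best <- fits[[length(fits)]]
  files <- character(0)

  # trajectories by state x material
  tr <- posterior_trajectories(best)
  f_csv <- file.path(out_dir, "trajectories.csv")
  utils::write.csv(tr, f_csv, row.names = FALSE)
  g <- ggplot2::ggplot(tr, ggplot2::aes(x = time_min, y = mean,
                                        colour = state)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = lo, ymax = hi, fill = state),
                         alpha = 0.15, colour = NA) +
    ggplot2::facet_grid(parameter ~ material, scales = "free_y") +
    ggplot2::scale_y_continuous(
      labels = function(v) signif(exp(v), 3)) +
    ggplot2::labs(x = "time (min)", y = "predicted mean (original units)") +
    ggplot2::theme_minimal()
  f_fig <- file.path(out_dir, "trajectories.pdf")
  ggplot2::ggsave(f_fig, g, width = 8, height = 9)
  files <- c(files, f_csv, f_fig)

  # posterior ellipses at time 0, per manufacturing state
  ell_rows <- list()
  for (st in c("UW", "GS", "SF")) {
    es <- posterior_ellipses(best, time_min = 0, state = st)
    for (e in es) {
      ell_rows[[length(ell_rows) + 1L]] <- data.frame(
        state = st, pair = paste(e$pair, collapse = ":"),
        x = e$polygon[, 1], y = e$polygon[, 2],
        x_param = e$pair[1], y_param = e$pair[2])
    }
  }
  ed <- do.call(rbind, ell_rows)
  f_csv <- file.path(out_dir, "ellipses_t0.csv")
  utils::write.csv(ed, f_csv, row.names = FALSE)
  g2 <- ggplot2::ggplot(ed, ggplot2::aes(x = x, y = y, colour = state)) +
    ggplot2::geom_path() +
    ggplot2::facet_wrap(~pair, scales = "free", ncol = 3) +
    ggplot2::labs(x = "log value (labels: original units)", y = NULL) +
    ggplot2::scale_x_continuous(labels = function(v) signif(exp(v), 3)) +
    ggplot2::scale_y_continuous(labels = function(v) signif(exp(v), 3)) +
    ggplot2::theme_minimal()
  f_fig <- file.path(out_dir, "ellipses_t0.pdf")
  ggplot2::ggsave(f_fig, g2, width = 9, height = 6)
  files <- c(files, f_csv, f_fig)

  # QQ plot of scaled Mahalanobis distances
  gof <- mahalanobis_gof(best)
  f_csv <- file.path(out_dir, "gof_qq_report.csv")
  utils::write.csv(gof, f_csv, row.names = FALSE)
  g3 <- ggplot2::ggplot(gof, ggplot2::aes(theoretical, observed)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "F-distribution quantile", y = "scaled distance d2/p") +
    ggplot2::theme_minimal()
  f_fig <- file.path(out_dir, "gof_qq.pdf")
  ggplot2::ggsave(f_fig, g3, width = 5, height = 5)
  files <- c(files, f_csv, f_fig)

  if (length(fits) > 1L) {
    wt <- waic_table(fits)
    f_csv <- file.path(out_dir, "waic_report.csv")
    utils::write.csv(wt, f_csv, row.names = FALSE)
    files <- c(files, f_csv)
  }
  invisible(files)
}
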