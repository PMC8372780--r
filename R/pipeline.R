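#' Run a full analysis pipeline
#'
#' Wires the stages together for a whole data set: reduced spectral density
#' mapping, per-residue model selection by AICc, and one of three
#' uncertainty procedures: `"mc"` (conventional analysis, Monte Carlo
#' uncertainties for the fixed optimal model), `"boot"` (same selection,
#' conventional enumerated-bootstrap uncertainties), or `"bag"` (bootstrap
#' aggregation: smoothed parameters, plug-in smoothed uncertainties and
#' model fractions).  All modes write the spectral density table and the
#' per-model AICc table; times are reported in ns and spectral densities in
#' ns/rad in all output files.
#'
#' @param input path to a relaxation CSV/TSV, or a data.frame in the
#'   [read_relaxation()] layout.
#' @param mode `"mc"`, `"boot"` or `"bag"`.
#' @param config an [mf_config()] object.
#' @param out_dir output directory (created if missing); set `NULL` to
#'   skip writing files.
#' @param seed integer seed (used by the Monte Carlo stage; the enumerated
#'   bootstrap ensemble is deterministic and needs none).
#' @param ensemble_dump also write the ensemble audit table
#'   (`ensemble.csv`: i, l, m, n, counter vector) in bootstrap modes.
#' @return List with `jw` (mapped table), `selection` (per-residue,
#'   per-model table), `params` (mode-specific result table), `mode`, `B`,
#'   `log` (character vector of log lines).
#' @export
run_pipeline <- function(input, mode = c("mc", "boot", "bag"),
                         config = mf_config(), out_dir = NULL, seed = 1,
                         ensemble_dump = FALSE) {
  mode <- match.arg(mode)
  df <- if (is.character(input)) read_relaxation(input) else {
    validate_relaxation(input); input
  }
  G <- length(unique(df$field_MHz))
  if (G < 3)
    stop("G = ", G, " static magnetic fields found; the enumerated block ",
         "bootstrap needs at least 3 fields for a meaningful ensemble ",
         "(G = 3 gives 7^3 = 343 samples)")
  n_arr <- enumerate_block_arrangements(G)$n_arr
  B <- n_arr^3
  N <- 3L * G
  logln <- c(sprintf("bagmf pipeline: mode=%s seed=%d", mode, seed),
             sprintf("G=%d fields, N=%d raw spectral density values, B=%d",
                     G, N, B))

  jw <- map_relaxation_to_jw(df, config$constants)
  sets <- spectral_density_sets(jw, config)
  logln <- c(logln, sprintf("%d residues mapped; fit vector length %d",
                            length(sets), 1 + 2 * G))

  sel_rows <- list()
  par_rows <- list()
  dropped_total <- 0L
  for (sds in sets) {
    sel <- select_model(sds, config)
    tab <- sel$table
    st <- data.frame(residue = sds$residue, tab)
    st$chi2 <- ifelse(is.na(tab$chi2), "NA", formatC(tab$chi2, digits = 6,
                                                     format = "g"))
    st$aicc <- ifelse(is.na(tab$aicc), "NA", formatC(tab$aicc, digits = 6,
                                                     format = "g"))
    sel_rows[[length(sel_rows) + 1L]] <-
      st[, c("residue", "model", "chi2", "k", "aicc", "best")]
    logln <- c(logln, sprintf("residue %s: best model %d (AICc %s)",
                              sds$residue, sel$best,
                              formatC(sel$fit$aicc, digits = 4,
                                      format = "g")))

    p <- sel$fit$params
    base <- data.frame(residue = sds$residue, model = sel$best,
                       tau_m = p$tau_m * 1e9, Sf2 = p$Sf2, Ss2 = p$Ss2,
                       tau_f = p$tau_f * 1e9, tau_s = p$tau_s * 1e9,
                       S2 = p$S2)
    if (mode == "mc") {
      mc <- monte_carlo_sd(sds, sel, n_sims = config$n_mc,
                           seed = seed + as.integer(sds$residue),
                           config = config)
      sd_ns <- mc$sd * c(1e9, 1, 1, 1e9, 1e9, 1)
      names(sd_ns) <- paste0(names(mc$sd), "_sd")
      par_rows[[length(par_rows) + 1L]] <-
        cbind(base, as.data.frame(as.list(sd_ns)))
      dropped_total <- dropped_total + mc$n_dropped
    } else if (mode == "boot") {
      bt <- conventional_bootstrap_sd(sds, sel, config)
      sd_ns <- bt$sd * c(1e9, 1, 1, 1e9, 1e9, 1)
      names(sd_ns) <- paste0(names(bt$sd), "_sd")
      par_rows[[length(par_rows) + 1L]] <-
        cbind(base, as.data.frame(as.list(sd_ns)))
      dropped_total <- dropped_total + bt$n_dropped
    } else {
      bag <- bagged_fit(sds, config, selection = sel, keep_matrices = FALSE)
      mu <- bag$smoothed * c(1e9, 1, 1, 1e9, 1e9, 1)
      ssd <- bag$smoothed_sd * c(1e9, 1, 1, 1e9, 1e9, 1)
      usd <- bag$naive_sd * c(1e9, 1, 1, 1e9, 1e9, 1)
      row <- data.frame(residue = sds$residue, best_model = sel$best,
                        t(bag$model_fractions),
                        t(stats::setNames(mu, names(mu))),
                        t(stats::setNames(ssd, paste0(names(ssd), "_sd"))),
                        t(stats::setNames(usd, paste0(names(usd), "_sd_u"))),
                        S2_product = bag$S2_product, B = bag$B_used)
      par_rows[[length(par_rows) + 1L]] <- row
      dropped_total <- dropped_total + (bag$B - bag$B_used)
    }
  }
  selection <- do.call(rbind, sel_rows)
  params <- do.call(rbind, par_rows)
  logln <- c(logln, sprintf("dropped replicates: %d", dropped_total))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jw_out <- jw
    jcols <- c("J0", "J0_err", "JwN", "JwN_err", "JwH087", "JwH087_err")
    jw_out[jcols] <- jw_out[jcols] * 1e9
    utils::write.csv(jw_out[c("residue", "field_MHz", jcols)],
                     file.path(out_dir, "jw.csv"), row.names = FALSE)
    utils::write.csv(selection, file.path(out_dir, "selection.csv"),
                     row.names = FALSE)
    utils::write.csv(params,
                     file.path(out_dir, paste0("params_", mode, ".csv")),
                     row.names = FALSE)
    if (ensemble_dump && mode %in% c("boot", "bag")) {
      arr <- enumerate_block_arrangements(G)
      idx <- t(vapply(seq_len(B), index_to_block_indices,
                      integer(3), n_arr = arr$n_arr))
      Y <- cbind(arr$counter[idx[, 1], ], arr$counter[idx[, 2], ],
                 arr$counter[idx[, 3], ])
      colnames(Y) <- paste0("Y", seq_len(N))
      utils::write.csv(data.frame(i = seq_len(B), l = idx[, 1],
                                  m = idx[, 2], n = idx[, 3], Y),
                       file.path(out_dir, "ensemble.csv"),
                       row.names = FALSE)
    }
    writeLines(logln, file.path(out_dir, "run.log"))
  }
  list(jw = jw, selection = selection, params = params,
       mode = mode, B = B, log = logln)
}

#' Command-line entry point
#'
#' Subcommand interface used by the `inst/cli/bagmf.R` script:
#' \itemize{
#'   \item `simulate --scenario gcn4like --seed S -o DIR` writes
#'     `rates.csv` and `truth.csv` for the synthetic scenario;
#'   \item `mapjw -i rates.csv -o DIR` writes the mapped `jw.csv`;
#'   \item `fit --mode mc|boot|bag -i rates.csv -o DIR [--config cfg.json]
#'     [--seed S]` runs the full pipeline;
#'   \item `report -i params_bag.csv` prints a short summary.
#' }
#' The optional JSON config may set `tau_m_fixed_ns`,
#' `fixed_tau_m_residues`, `threshold_ns`, `n_mc` and
#' `smoothed_sd_scale_by_N`.
#'
#' @param argv character vector of command-line arguments (defaults to the
#'   process arguments).
#' @return Invisibly, the result of the subcommand.
#' @export
bagmf_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  if (!length(argv))
    stop("usage: bagmf <simulate|mapjw|fit|report> [options]")
  sub <- argv[1]
  argv <- argv[-1]
  optlist <- list(
    optparse::make_option("--scenario", type = "character",
                          default = "gcn4like"),
    optparse::make_option("--mode", type = "character", default = "bag"),
    optparse::make_option(c("-i", "--input"), type = "character",
                          default = NULL),
    optparse::make_option(c("-o", "--out"), type = "character",
                          default = "."),
    optparse::make_option("--config", type = "character", default = NULL),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--ensemble-dump", action = "store_true",
                          default = FALSE, dest = "ensemble_dump"))
  opt <- optparse::parse_args(optparse::OptionParser(option_list = optlist),
                              args = argv)

  config <- mf_config()
  if (!is.null(opt$config)) {
    cj <- jsonlite::read_json(opt$config, simplifyVector = TRUE)
    args <- list()
    if (!is.null(cj$tau_m_fixed_ns)) args$tau_m_fixed <- cj$tau_m_fixed_ns * 1e-9
    if (!is.null(cj$threshold_ns)) args$threshold <- cj$threshold_ns * 1e-9
    if (!is.null(cj$fixed_tau_m_residues))
      args$fixed_tau_m_residues <- cj$fixed_tau_m_residues
    if (!is.null(cj$n_mc)) args$n_mc <- cj$n_mc
    if (!is.null(cj$smoothed_sd_scale_by_N))
      args$smoothed_sd_scale_by_N <- cj$smoothed_sd_scale_by_N
    config <- do.call(mf_config, args)
  }

  if (sub == "simulate") {
    if (opt$scenario != "gcn4like")
      stop("unknown scenario: ", opt$scenario)
    ds <- generate_dataset(gcn4_like_scenario(opt$seed))
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(ds$data, file.path(opt$out, "rates.csv"),
                     row.names = FALSE)
    truth <- ds$truth
    truth[c("tau_m", "tau_f", "tau_s")] <-
      truth[c("tau_m", "tau_f", "tau_s")] * 1e9
    utils::write.csv(truth, file.path(opt$out, "truth.csv"),
                     row.names = FALSE)
    message("wrote rates.csv and truth.csv (times in ns) to ", opt$out)
    return(invisible(ds))
  }
  if (sub == "mapjw") {
    if (is.null(opt$input)) stop("mapjw requires -i")
    jw <- map_relaxation_to_jw(read_relaxation(opt$input),
                               config$constants)
    jcols <- c("J0", "J0_err", "JwN", "JwN_err", "JwH087", "JwH087_err")
    jw[jcols] <- jw[jcols] * 1e9
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(jw[c("residue", "field_MHz", jcols)],
                     file.path(opt$out, "jw.csv"), row.names = FALSE)
    message("wrote jw.csv (ns/rad) to ", opt$out)
    return(invisible(jw))
  }
  if (sub == "fit") {
    if (is.null(opt$input)) stop("fit requires -i")
    res <- run_pipeline(opt$input, mode = opt$mode, config = config,
                        out_dir = opt$out, seed = opt$seed,
                        ensemble_dump = opt$ensemble_dump)
    message("mode ", res$mode, ": B = ", res$B, "; outputs in ", opt$out)
    return(invisible(res))
  }
  if (sub == "report") {
    if (is.null(opt$input)) stop("report requires -i")
    tab <- utils::read.csv(opt$input)
    print(utils::head(tab, 20))
    message(nrow(tab), " residues in ", opt$input)
    return(invisible(tab))
  }
  stop("unknown subcommand: ", sub)
}
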