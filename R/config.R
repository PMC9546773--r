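#' Serialize a recognition model to JSON
#'
#' Round-trippable, versioned model format: alphabet, per-mode geometry
#' and coefficients (by named feature), interactions (offset/orientation
#' grids of log cooperativities), per-column activities, and an optional
#' absolute scale block (K_D or catalytic-efficiency units).
#'
#' @param model A [recognition_model()] (or a `probefit` result, whose
#'   model and activities are exported).
#' @param path Output JSON path.
#' @param scale Optional absolute-scale block (list), e.g.
#'   `list(kind = "kd", p_free = ..., units = "nM")`.
#' @export
write_model <- function(model, path, scale = NULL) {
  if (inherits(model, "probefit")) {
    fit <- model
    model <- fit$model
    acts <- fit$acts
  } else acts <- NULL
  alph <- model$modes[[1L]]$alphabet
  js <- list(
    format = "probefit-model", version = 1L,
    alphabet = list(letters = alph$letters,
                    complement = as.list(alph$complement)),
    modes = lapply(model$modes, function(m) list(
      L = m$L, f = m$f, strands = m$strands,
      rc_symmetric = m$rc_symmetric, reference = m$reference,
      beta_mono = unname(m$beta_mono),
      pairs = unname(as.matrix(m$pairs)),
      beta_pair = lapply(m$beta_pair, unname),
      position_bias = if (!is.null(m$position_bias))
        unname(m$position_bias))),
    interactions = lapply(model$interactions, function(it) list(
      a = it$a, b = it$b, max_spacing = it$max_spacing, clash = it$clash,
      translational_tie = it$translational_tie,
      log_omega = unname(it$log_omega))),
    log_alpha = unname(model$log_alpha),
    log_alpha_int = if (!is.null(model$log_alpha_int))
      unname(model$log_alpha_int),
    log_alpha_ns = model$log_alpha_ns,
    activities = acts,
    scale = scale)
  jsonlite::write_json(js, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  if (!identical(js$format, "probefit-model"))
    stop("not a recognition-model JSON file")
  comp <- if (length(js$alphabet$complement)) unlist(js$alphabet$complement)
  alph <- pf_alphabet(js$alphabet$letters, comp)
  get_modes <- function(ms) {
    lapply(ms, function(m) {
      pr <- if (length(m$pairs)) matrix(as.integer(as.matrix(m$pairs)), ncol = 2L)
            else "none"
      bp <- m$beta_pair
      # a list of equal-sized coupling matrices may come back as a 3-D array
      if (is.array(bp) && length(dim(bp)) == 3L)
        bp <- lapply(seq_len(dim(bp)[1L]), function(i) bp[i, , ])
      binding_mode(m$L, alph, f = m$f, strands = m$strands,
                   beta_mono = as.matrix(m$beta_mono),
                   pairs = pr,
                   beta_pair = if (length(bp)) lapply(bp, as.matrix),
                   position_bias = if (!is.null(m$position_bias))
                     as.matrix(m$position_bias),
                   rc_symmetric = isTRUE(m$rc_symmetric),
                   reference = m$reference)
    })
  }
  modes <- get_modes(js$modes)
  ints <- lapply(js$interactions, function(it)
    cooperativity(it$a, it$b, max_spacing = it$max_spacing, clash = it$clash,
                  log_omega = as.matrix(it$log_omega),
                  translational_tie = isTRUE(it$translational_tie)))
  recognition_model(modes, ints,
                    log_alpha = as.matrix(js$log_alpha),
                    log_alpha_ns = js$log_alpha_ns,
                    log_alpha_int = if (!is.null(js$log_alpha_int))
                      as.matrix(js$log_alpha_int))
}

#' Run configurations
#'
#' `read_run_config()` reads and validates a JSON run configuration,
#' filling defaults (barrier at 40, the standard Dirichlet grid, bin sizes
#' 500/10) and rejecting unknown keys with a message naming the offender.
#' `run_config()` dispatches a validated configuration to the matching
#' front end (`fit`, `kdseq`, `kinase`, `qc`, `simulate`) and writes
#' artifacts (model JSON, report JSON, the effective configuration and
#' seeds) into the output directory.
#'
#' @param path JSON file path.
#' @return A validated config (class `"run_config"`).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

config_defaults <- function() {
  list(seed = 1L, verbosity = "INFO", out_dir = ".",
       regularization = list(lambda = 1e-6, k_dirichlet = 0, theta_max = 40),
       optimizer = list(maxit = 500L, pgtol = 1e-6),
       dirichlet_grid = c(0, 10, 20, 50, 100, 200, 500, 1000, 2000),
       bin_size_selex = 500L, bin_size_array = 10L)
}

#' @rdname read_run_config
#' @param cfg A configuration list.
#' @export
validate_run_config <- function(cfg) {
  known <- c("subcommand", "experiments", "regularization", "optimizer",
             "out_dir", "seed", "verbosity", "modes", "interactions",
             "selection", "p_total", "dna_input", "times", "enzyme_conc",
             "truth", "depth", "dirichlet_grid", "bin_size_selex",
             "bin_size_array", "force")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown configuration key: ", paste(bad, collapse = ", "))
  if (is.null(cfg$subcommand) ||
      !cfg$subcommand %in% c("fit", "kdseq", "kinase", "qc", "simulate", "logo"))
    stop("configuration key 'subcommand' must name a front end")
  def <- config_defaults()
  for (nm in names(def))
    if (is.null(cfg[[nm]])) cfg[[nm]] <- def[[nm]]
  for (nm in names(def$regularization))
    if (is.null(cfg$regularization[[nm]]))
      cfg$regularization[[nm]] <- def$regularization[[nm]]
  if (cfg$subcommand %in% c("fit", "kdseq", "qc", "kinase")) {
    if (is.null(cfg$experiments) || !length(cfg$experiments))
      stop("configuration key 'experiments' is required for ", cfg$subcommand)
    exs <- cfg$experiments
    if (is.data.frame(exs)) exs <- split(exs, seq_len(nrow(exs)))
    for (ex in exs) {
      if (is.null(ex$table)) stop("experiment block missing key 'table'")
      if (!file.exists(ex$table)) stop("table file not found: ", ex$table)
    }
  }
  structure(cfg, class = "run_config")
}

#' @rdname read_run_config
#' @export
run_config <- function(cfg) {
  if (!inherits(cfg, "run_config")) cfg <- validate_run_config(cfg)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(cfg), file.path(cfg$out_dir, "effective-config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  reg <- reg_spec(cfg$regularization$lambda, cfg$regularization$k_dirichlet,
                  cfg$regularization$theta_max)
  ctrl <- cfg$optimizer
  exs <- cfg$experiments
  if (is.data.frame(exs)) exs <- split(exs, seq_len(nrow(exs)))
  load_tables <- function() lapply(exs, function(ex) read_count_table(ex$table))
  sel_of <- function(ex, tb) {
    s <- ex$selection
    if (is.null(s)) s <- cfg$selection
    selection_spec(s$family,
                   rho = if (!is.null(s$rho)) unlist(s$rho) else 1,
                   gamma = if (!is.null(s$gamma)) unlist(s$gamma) else 0,
                   delta = if (!is.null(s$delta)) unlist(s$delta),
                   n_columns = ncol(tb$counts))
  }
  out <- switch(cfg$subcommand,
    fit = {
      tabs <- load_tables()
      sels <- Map(sel_of, exs, tabs)
      qcres <- lapply(tabs, kl_enrichment_filter)
      if (!isTRUE(cfg$force) && !all(vapply(qcres, `[[`, TRUE, "pass")))
        stop("input table fails the enrichment filter; rerun with force = true")
      fit <- probefit(tabs, sels, reg = reg,
                      modes = if (!is.null(cfg$modes$n)) cfg$modes$n else 1L,
                      L = if (!is.null(cfg$modes$L)) cfg$modes$L else 8,
                      seed = cfg$seed, control = ctrl)
      write_model(fit, file.path(cfg$out_dir, "model.json"))
      utils::write.table(
        data.frame(step = seq_along(fit$trace), objective = fit$trace),
        file.path(cfg$out_dir, "objective-trace.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      fit
    },
    kdseq = {
      tabs <- load_tables()
      fit <- kdseq_fit(tabs[[1L]], tabs[[2L]], tabs[[3L]],
                       p_total = cfg$p_total, dna_input = cfg$dna_input,
                       reg = reg, seed = cfg$seed, control = ctrl)
      write_model(fit, file.path(cfg$out_dir, "model.json"),
                  scale = list(kind = "kd", units = "nM",
                               p_free = fit$p_free_protein,
                               p_bound = fit$p_bound))
      jsonlite::write_json(fit$diagnostics,
                           file.path(cfg$out_dir, "diagnostics.json"),
                           auto_unbox = TRUE, digits = NA)
      fit
    },
    kinase = {
      paths <- vapply(exs, function(e) as.character(e$table), "")
      tabs <- lapply(paths, read_count_table)
      fit <- keff_fit(tabs, times = unlist(cfg$times),
                      enzyme_conc = cfg$enzyme_conc, seed = cfg$seed)
      write_model(fit, file.path(cfg$out_dir, "model.json"),
                  scale = list(kind = "keff", scale = fit$keff_scale))
      fit
    },
    qc = {
      tabs <- load_tables()
      rep <- lapply(tabs, kl_enrichment_filter)
      jsonlite::write_json(rep, file.path(cfg$out_dir, "qc-report.json"),
                           auto_unbox = TRUE, digits = NA, null = "null")
      rep
    },
    stop("subcommand '", cfg$subcommand, "' must be driven through the R API"))
  invisible(out)
}
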