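# Readers and writers for the package's delimited formats. All files are
# comma-separated UTF-8 with a header row; energies are kcal/mol.

read_checked <- function(path, col_spec, what) {
  if (!file.exists(path)) {
    abort_io(paste0(what, " file not found: ", path))
  }
  # readr's own parsing chatter is superseded by the typed errors below
  tbl <- tryCatch(
    suppressWarnings(
      readr::read_csv(path, col_types = col_spec, progress = FALSE,
                      lazy = FALSE)),
    error = function(e) {
      abort_parse(paste0("failed to parse ", what, " file ", path, ": ",
                         conditionMessage(e)))
    }
  )
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort_parse(paste0(
      "malformed ", what, " file ", path, ": row ", probs$row[1],
      ", column ", probs$col[1], " (", probs$expected[1], ")"))
  }
  miss <- setdiff(names(col_spec$cols), names(tbl))
  if (length(miss) > 0) {
    abort_parse(paste0(
      what, " file ", path, " is missing column(s): ",
      paste(miss, collapse = ", ")))
  }
  tbl
}

#' Read and write per-conformation effect (ddG) tables
#'
#' The on-disk format is CSV with header `site,wt,mut,conformation,dG`
#' (energies kcal/mol). Reading validates the table ([validate_ddg_table()]);
#' when a `conformations` set is supplied, mutations must cover it, unless
#' `fill_missing = TRUE`, in which case missing entries are filled with
#' `dG = 0` under a warning (useful when a table omits a conformation that
#' mutations are assumed not to touch).
#'
#' @param path File path.
#' @param conformations Optional conformation set the table must cover.
#' @param fill_missing Fill missing conformation entries with 0 instead of
#'   erroring.
#' @return `read_ddg_table()`: a validated ddG tibble. `write_ddg_table()`:
#'   the input, invisibly.
#' @export
read_ddg_table <- function(path, conformations = NULL, fill_missing = FALSE) {
  spec <- readr::cols(
    site = readr::col_integer(),
    wt = readr::col_character(),
    mut = readr::col_character(),
    conformation = readr::col_character(),
    dG = readr::col_double()
  )
  tbl <- read_checked(path, spec, "ddG table")
  if (!is.null(conformations) && fill_missing) {
    id <- mutation_label(tbl$wt, tbl$site, tbl$mut)
    have <- split(tbl$conformation, id)
    missing <- lapply(have, function(x) setdiff(conformations, x))
    n_fill <- sum(lengths(missing))
    if (n_fill > 0) {
      warn(sprintf(
        "filling %d missing conformation entr%s with dG = 0",
        n_fill, if (n_fill == 1) "y" else "ies"))
      first <- tbl[!duplicated(id), , drop = FALSE]
      first_id <- id[!duplicated(id)]
      fill <- purrr::map_dfr(seq_len(nrow(first)), function(i) {
        mc <- missing[[first_id[i]]]
        if (length(mc) == 0) return(NULL)
        tibble::tibble(
          site = first$site[i], wt = first$wt[i], mut = first$mut[i],
          conformation = mc, dG = 0
        )
      })
      tbl <- dplyr::bind_rows(tbl, fill)
    }
  }
  validate_ddg_table(tbl, conformations = conformations)
  tbl
}

#' @rdname read_ddg_table
#' @param ddg_table A ddG table to write.
#' @export
write_ddg_table <- function(ddg_table, path) {
  validate_ddg_table(ddg_table)
  readr::write_csv(ddg_table, path)
  invisible(ddg_table)
}

#' Read and write within-conformation coupling tables
#'
#' CSV with header
#' `site_a,wt_a,mut_a,site_b,wt_b,mut_b,conformation,ddG` (kcal/mol);
#' `mut_a`/`mut_b` are the mutant residues. The two sites of each row must
#' differ.
#'
#' @param path File path.
#' @return `read_coupling_table()`: a validated coupling tibble.
#' @export
read_coupling_table <- function(path) {
  spec <- readr::cols(
    site_a = readr::col_integer(),
    wt_a = readr::col_character(),
    mut_a = readr::col_character(),
    site_b = readr::col_integer(),
    wt_b = readr::col_character(),
    mut_b = readr::col_character(),
    conformation = readr::col_character(),
    ddG = readr::col_double()
  )
  tbl <- read_checked(path, spec, "coupling table")
  if (any(tbl$site_a == tbl$site_b)) {
    abort_invalid_input("coupling rows must pair mutations at distinct sites.")
  }
  tbl
}

#' @rdname read_coupling_table
#' @param couplings A coupling table to write.
#' @export
write_coupling_table <- function(couplings, path) {
  readr::write_csv(couplings, path)
  invisible(couplings)
}

#' Read and write per-pair DMS results
#'
#' CSV serialisation of the `pairs` tibble of a [run_dms()] result; columns
#' round-trip exactly.
#'
#' @param path File path.
#' @param pairs A per-pair results tibble.
#' @return The tibble (read) or the input, invisibly (write).
#' @export
write_pair_results <- function(pairs, path) {
  readr::write_csv(pairs, path)
  invisible(pairs)
}

#' @rdname write_pair_results
#' @export
read_pair_results <- function(path) {
  spec <- readr::cols(
    mut_a = readr::col_character(),
    mut_b = readr::col_character(),
    site_a = readr::col_integer(),
    site_b = readr::col_integer(),
    mu_peak = readr::col_double(),
    epsilon_peak = readr::col_double(),
    class_peak = readr::col_character(),
    class_raw = readr::col_character(),
    n_switches = readr::col_integer()
  )
  read_checked(path, spec, "pair results")
}

#' Serialise a DMS summary to JSON
#'
#' Writes the cutoff sweep, the fraction-at-or-above-cutoff curve, the
#' switch fraction and the peak-epistasis histogram as a single JSON object
#' with stable key order; `read_dms_summary()` restores an equivalent
#' `dms_summary` object.
#'
#' @param summary A [summarize_dms()] result.
#' @param path File path.
#' @return The summary (read) or the input, invisibly (write).
#' @export
write_dms_summary <- function(summary, path) {
  if (!inherits(summary, "dms_summary")) {
    abort_invalid_input("`summary` must be a dms_summary object.")
  }
  payload <- list(
    n_pairs = summary$n_pairs,
    sweep = as.data.frame(summary$sweep),
    fraction_ge = as.data.frame(summary$fraction_ge),
    switch_cutoff = summary$switch_cutoff,
    switch_fraction = summary$switch_fraction,
    histogram = as.data.frame(summary$histogram)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(summary)
}

#' @rdname write_dms_summary
#' @export
read_dms_summary <- function(path) {
  if (!file.exists(path)) {
    abort_io(paste0("summary file not found: ", path))
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      n_pairs = x$n_pairs,
      sweep = tibble::as_tibble(x$sweep),
      fraction_ge = tibble::as_tibble(x$fraction_ge),
      switch_cutoff = x$switch_cutoff,
      switch_fraction = x$switch_fraction %||% NA_real_,
      histogram = tibble::as_tibble(x$histogram)
    ),
    class = "dms_summary"
  )
}

run_config_keys <- function() {
  c("conformations", "active", "G0", "stoich", "temperature",
    "gas_constant", "ligand", "mu_grid", "mu_base", "cutoff", "cutoffs",
    "sign_tol", "seed")
}

#' Read a run configuration (YAML or JSON)
#'
#' A run configuration defines an ensemble and the titration/analysis
#' parameters in one file. Recognised keys: `conformations`, `active`, `G0`,
#' `stoich` (map conformation -> map ligand -> count), `temperature`,
#' `gas_constant`, `ligand`, `mu_grid` (either a list of values or a map
#' with `from`, `to`, `by`), `mu_base` (map ligand -> potential), `cutoff`,
#' `cutoffs`, `sign_tol`, `seed`. Unknown keys are rejected so typos cannot
#' silently change an analysis.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of validated settings; the assembled `ens_def` is in
#'   `$ensemble`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort_io(paste0("config file not found: ", path))
  }
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(cfg), run_config_keys())
  if (length(unknown) > 0) {
    abort_invalid_input(paste0(
      "unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  need <- c("conformations", "active", "G0")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0) {
    abort_invalid_input(paste0(
      "config is missing key(s): ", paste(miss, collapse = ", ")))
  }
  stoich <- NULL
  if (!is.null(cfg$stoich)) {
    stoich <- lapply(cfg$stoich, function(s) unlist(s))
  }
  cfg$ensemble <- define_ensemble(
    conformations = as.character(unlist(cfg$conformations)),
    G0 = as.numeric(unlist(cfg$G0)),
    active = as.character(unlist(cfg$active)),
    stoich = stoich,
    temperature = cfg$temperature %||% DEFAULT_TEMPERATURE,
    gas_constant = cfg$gas_constant %||% R_KCAL
  )
  if (!is.null(cfg$mu_grid) && is.list(cfg$mu_grid) &&
      all(c("from", "to", "by") %in% names(cfg$mu_grid))) {
    cfg$mu_grid <- seq(cfg$mu_grid$from, cfg$mu_grid$to, by = cfg$mu_grid$by)
  } else if (!is.null(cfg$mu_grid)) {
    cfg$mu_grid <- as.numeric(unlist(cfg$mu_grid))
  }
  if (!is.null(cfg$mu_base)) {
    cfg$mu_base <- unlist(cfg$mu_base)
  }
  cfg
}
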