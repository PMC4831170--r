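scenario_to_list <- function(scenario) {
  sc <- unclass(scenario)
  sc$strategies <- lapply(sc$strategies, function(st) {
    st <- unclass(st)
    st$or_vs_reference <- if (is.na(st$or_vs_reference)) NULL else st$or_vs_reference
    st
  })
  if (!is.null(sc$life_table)) {
    sc$life_table <- list(age = sc$life_table$age,
                          p_annual = sc$life_table$p_annual)
  }
  if (!is.null(sc$transitions$matrices)) {
    sc$transitions$matrices <- lapply(sc$transitions$matrices, function(m) {
      apply(m, 1, function(r) as.list(r), simplify = FALSE)
    })
  }
  sc
}

list_to_scenario <- function(x) {
  # NULL fields serialise as empty containers in YAML/JSON; restore them
  nz <- function(v) if (length(v) == 0) NULL else v
  x$life_table <- nz(x$life_table)
  x$horizon_years <- nz(x$horizon_years)
  x$baseline <- nz(x$baseline)
  x$mortality$rr_combined <- nz(x$mortality$rr_combined)
  x$transitions$matrices <- nz(x$transitions$matrices)
  x$utilities$bse <- nz(unlist(x$utilities$bse))
  x$utilities$wse <- nz(unlist(x$utilities$wse))
  x$strategies <- lapply(x$strategies, function(st) {
    strategy(
      name = st$name,
      list_price = st$list_price,
      rebate = st$rebate %||% 0,
      price = st$price %||% net_price(st$list_price, st$rebate %||% 0),
      injections = lapply(st$injections, unlist),
      monitoring = lapply(st$monitoring, unlist),
      or_vs_reference = st$or_vs_reference %||% NA_real_,
      n_treatment_years = st$n_treatment_years %||% 3
    )
  })
  if (!is.null(x$life_table)) {
    x$life_table <- tibble(age = as.integer(unlist(x$life_table$age)),
                           p_annual = unlist(x$life_table$p_annual))
  }
  if (!is.null(x$transitions$matrices)) {
    x$transitions$matrices <- lapply(x$transitions$matrices, function(m) {
      do.call(rbind, lapply(m, unlist))
    })
  }
  for (f in c("band_edges", "baseline")) {
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  }
  for (f in c("improvement_bias", "bse_anchors", "wse_anchors",
              "recruitment_window")) {
    if (!is.null(x$synthetic[[f]])) x$synthetic[[f]] <- unlist(x$synthetic[[f]])
  }
  args <- x[intersect(names(x), names(formals(dme_scenario)))]
  do.call(dme_scenario, args)
}

#' Write a scenario file
#'
#' Scenarios are stored as YAML mirroring the scenario structure
#' field-for-field (strategies, costs, utilities, transitions, synthetic
#' settings, seed), so a run is reproducible from the file alone.
#'
#' @param scenario A `dme_scenario`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(scenario, path) {
  yaml::write_yaml(scenario_to_list(scenario), path,
                   precision = 15L)
  invisible(path)
}

#' Read and validate a scenario file
#'
#' @param path YAML scenario file written by [write_scenario()] (or
#'   hand-authored in the same layout).
#' @return A validated `dme_scenario`.
#' @export
read_scenario <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("scenario file '%s' does not exist.", path))
  }
  list_to_scenario(yaml::read_yaml(path))
}

#' Results in a cost-utility table layout
#'
#' One row per reported quantity, one column per strategy, one column per
#' comparison: discounted costs, years without visual impairment, QALYs,
#' then the incremental cost per year without visual impairment, cost per
#' QALY (or a dominance label) and net monetary benefit.
#'
#' @param res A `dme_cea`.
#' @return A tibble.
#' @export
cea_results_table <- function(res) {
  st <- res$strategies
  cmp <- res$comparisons
  quantity <- c("cost_eur", "years_without_vi", "total_qalys",
                "cost_per_year_without_vi", "cost_per_qaly", "nmb_eur")
  out <- tibble(quantity = quantity)
  for (i in seq_len(nrow(st))) {
    out[[st$strategy[i]]] <- c(st$cost[i], st$years_no_vi[i], st$qalys[i],
                               NA, NA, NA)
  }
  for (i in seq_len(nrow(cmp))) {
    col <- paste0(cmp$strategy[i], "_vs_", cmp$reference[i])
    out[[col]] <- c(cmp$delta_cost[i], cmp$delta_years_no_vi[i],
                    cmp$delta_qalys[i], cmp$cost_per_year_no_vi[i],
                    cmp$icer_value[i], cmp$nmb[i])
  }
  out
}

#' Run the pipeline and write a result bundle
#'
#' Executes the requested analyses on a scenario and writes plain-text
#' outputs to `out_dir`: per-strategy trace CSVs, the results table (CSV
#' and JSON), and a manifest (resolved key parameters, seed, package
#' version) sufficient to reproduce the run bit-for-bit.  Optional extras:
#' the tornado table, PSA draws with the acceptability curve, and
#' break-even prices.
#'
#' @param scenario A `dme_scenario` or a path to a scenario YAML file.
#' @param out_dir Output directory (created if missing).
#' @param analyses Subset of `c("run", "owsa", "psa", "threshold")`.
#' @param seed Optional override of the scenario seed.
#' @param horizon_years,wtp Optional overrides.
#' @param n_sims Optional PSA draw-count override.
#' @param threshold_strategies Strategies whose break-even price is
#'   searched (default: every non-reference strategy).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list of everything computed (`cea`, and the
#'   requested `owsa`, `psa`, `ceac`, `thresholds`) plus `files` written.
#' @export
run_pipeline <- function(scenario, out_dir,
                         analyses = "run",
                         seed = NULL, horizon_years = NULL, wtp = NULL,
                         n_sims = NULL,
                         threshold_strategies = NULL,
                         quiet = FALSE) {
  analyses <- match.arg(analyses, c("run", "owsa", "psa", "threshold"),
                        several.ok = TRUE)
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  validate_scenario(scenario)
  if (!is.null(seed)) scenario$seed <- seed
  if (!is.null(horizon_years)) scenario$horizon_years <- horizon_years
  if (!is.null(wtp)) scenario$wtp <- wtp
  if (!is.null(n_sims)) scenario$psa$n_sims <- n_sims
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  files <- character()
  out <- list()

  res <- run_cea(scenario)
  out$cea <- res
  say("run: horizon %d cycles, %d strategies, seed %d",
      res$resolved$horizon_cycles, nrow(res$strategies), scenario$seed)
  for (nm in names(res$traces)) {
    f <- file.path(out_dir, paste0("trace_", nm, ".csv"))
    readr::write_csv(as_tibble(res$traces[[nm]]), f)
    files <- c(files, f)
  }
  tab <- cea_results_table(res)
  f <- file.path(out_dir, "results.csv")
  readr::write_csv(tab, f); files <- c(files, f)
  f <- file.path(out_dir, "results.json")
  jsonlite::write_json(
    list(strategies = res$strategies, comparisons = res$comparisons),
    f, dataframe = "rows", auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  files <- c(files, f)

  if ("owsa" %in% analyses) {
    ow <- run_owsa(scenario)
    out$owsa <- ow
    say("owsa: %d parameters evaluated", length(unique(ow$parameter)))
    f <- file.path(out_dir, "owsa.csv")
    readr::write_csv(as_tibble(ow), f); files <- c(files, f)
  }
  if ("psa" %in% analyses) {
    say("psa: %d draws, seed %d", scenario$psa$n_sims, scenario$psa$seed)
    psa <- run_psa(scenario)
    ceac <- build_ceac(psa)
    out$psa <- psa
    out$ceac <- ceac
    f <- file.path(out_dir, "psa_draws.csv")
    readr::write_csv(psa$draws, f); files <- c(files, f)
    f <- file.path(out_dir, "ceac.csv")
    readr::write_csv(as_tibble(ceac), f); files <- c(files, f)
  }
  if ("threshold" %in% analyses) {
    threshold_strategies <- threshold_strategies %||%
      setdiff(names(scenario$strategies), scenario$reference_strategy)
    th <- lapply(threshold_strategies, function(nm) {
      v <- find_price_threshold(scenario, nm)
      say("threshold: %s breaks even at %.2f EUR", nm, as.numeric(v))
      list(strategy = nm, break_even_price = as.numeric(v),
           nmb_at_price = attr(v, "nmb"))
    })
    out$thresholds <- th
    f <- file.path(out_dir, "thresholds.json")
    jsonlite::write_json(th, f, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, f)
  }

  manifest <- list(
    package = "dmecea",
    version = as.character(utils::packageVersion("dmecea")),
    analyses = analyses,
    seed = scenario$seed,
    psa_seed = scenario$psa$seed,
    n_sims = scenario$psa$n_sims,
    wtp = scenario$wtp,
    discount_rate = scenario$discount$annual_rate,
    horizon_cycles = res$resolved$horizon_cycles,
    scenario = scenario_to_list(scenario)
  )
  f <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, f)

  out$files <- files
  invisible(out)
}
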