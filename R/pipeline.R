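#' Pipeline configuration
#'
#' Bundles stage thresholds and the simulation configuration (or an input
#' directory of previously written tables) for [run_pipeline()].
#'
#' @param sim A [sim_config()] used to generate inputs when `input_dir` is
#'   `NULL`.
#' @param input_dir Optional directory containing `motifs.tsv`,
#'   `proteins.fasta`, `sites.tsv`, `groups.csv`, `clinical.csv`,
#'   `growth.csv`; when given, inputs are read instead of simulated.
#' @param diff_fdr Differential selection threshold (default 0.15).
#' @param ksea_fdr,ksea_fdr_relaxed Strict / relaxed KSEA significance
#'   boundaries (defaults 0.05 and 0.25).
#' @param quartile H-score binarization quantile (default 0.75).
#' @param n_perm KSEA permutations.
#' @param metric,weight_p KSEA ranking metric and weight.
#' @param min_size,max_size Substrate-set size bounds.
#' @param kinases The signature kinases scored in the clinical stage.
#'
#' @return A list of class `pipeline_config` (validated).
#' @export
pipeline_config <- function(sim = sim_config(),
                            input_dir = NULL,
                            diff_fdr = 0.15,
                            ksea_fdr = 0.05,
                            ksea_fdr_relaxed = 0.25,
                            quartile = 0.75,
                            n_perm = 1000L,
                            metric = "signed_t",
                            weight_p = 1,
                            min_size = 5L,
                            max_size = 500L,
                            kinases = signature_kinases()) {
  cfg <- structure(list(sim = sim, input_dir = input_dir, diff_fdr = diff_fdr,
                        ksea_fdr = ksea_fdr, ksea_fdr_relaxed = ksea_fdr_relaxed,
                        quartile = quartile, n_perm = as.integer(n_perm),
                        metric = metric, weight_p = weight_p,
                        min_size = as.integer(min_size),
                        max_size = as.integer(max_size), kinases = kinases),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Checks that all thresholds lie in (0, 1), the kinase list is nonempty, and
#' any referenced input directory exists. Returns the config invisibly
#' unchanged, or aborts listing every violation.
#'
#' @param cfg A [pipeline_config()].
#' @return The validated config.
#' @export
validate_pipeline_config <- function(cfg) {
  errs <- character()
  for (th in c("diff_fdr", "ksea_fdr", "ksea_fdr_relaxed", "quartile")) {
    v <- cfg[[th]]
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1) {
      errs <- c(errs, sprintf("`%s` must lie in (0, 1); got %s.", th, format(v)))
    }
  }
  if (!length(cfg$kinases)) errs <- c(errs, "kinase list is empty.")
  if (cfg$n_perm < 1L) errs <- c(errs, "`n_perm` must be positive.")
  if (!is.null(cfg$input_dir) && !dir.exists(cfg$input_dir)) {
    errs <- c(errs, sprintf("input_dir does not exist: %s", cfg$input_dir))
  }
  if (!inherits(cfg$sim, "sim_config")) errs <- c(errs, "`sim` must be a sim_config.")
  if (length(errs)) abort(paste(c("invalid pipeline config:", errs), collapse = "\n  "))
  cfg
}

.stage <- function(name, code) {
  tryCatch(code, error = function(e) {
    abort(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
          parent = e)
  })
}

.require_file <- function(path) {
  if (!file.exists(path)) abort(sprintf("required input file not found: %s", path))
  path
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate (or load) -> log-transform -> differential selection
#' -> motif mapping -> KSEA -> quartile stratification -> pattern taxonomy ->
#' survival screen -> TGI, writing every result as TSV/CSV/JSON plus a config
#' snapshot and a log with input checksums into `out_dir`. All randomness is
#' governed by `cfg$sim$seed`, so two runs with the same config produce
#' byte-identical files.
#'
#' @param cfg A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#'
#' @return Invisibly, a list with the in-memory results (`diff`, `ksea`,
#'   `status`, `patterns`, `screen`, `tgi`, `km`) and `dir`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  validate_pipeline_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  log_lines <- character()
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  dat <- .stage("inputs", {
    if (is.null(cfg$input_dir)) {
      d <- simulate_cohort(cfg$sim)
      write_motifs(d$motifs, p("motifs.tsv"))
      write_fasta(d$proteins, p("proteins.fasta"))
      write_site_table(d$sites, p("sites.tsv"))
      readr::write_csv(d$groups, p("groups.csv"))
      write_clinical(d$clinical, p("clinical.csv"))
      write_growth(d$growth, p("growth.csv"))
      write_truth(d$truth, p("truth.json"))
      d
    } else {
      ip <- function(f) .require_file(file.path(cfg$input_dir, f))
      sites <- read_site_table(ip("sites.tsv"))
      groups <- readr::read_csv(ip("groups.csv"),
                                col_types = readr::cols(.default = readr::col_character()))
      attr(sites, "sample_groups") <- groups
      list(motifs = read_motifs(ip("motifs.tsv")),
           proteins = read_fasta(ip("proteins.fasta")),
           sites = sites, groups = groups,
           clinical = read_clinical(ip("clinical.csv")),
           growth = read_growth(ip("growth.csv")))
    }
  })
  for (f in c("motifs.tsv", "sites.tsv", "clinical.csv", "growth.csv")) {
    src <- if (is.null(cfg$input_dir)) p(f) else file.path(cfg$input_dir, f)
    if (file.exists(src)) {
      note("input %s md5 %s", f, unname(tools::md5sum(src)))
    }
  }

  lg <- .stage("log_transform", log2_transform(dat$sites))
  attr(lg, "sample_groups") <- dat$groups

  diff <- .stage("differential", phospho_diff(lg, dat$groups, fdr = cfg$diff_fdr))
  readr::write_tsv(diff, p("differential.tsv"), na = "")
  note("differential: %d/%d sites selected at q < %.2f",
       sum(diff$selected), sum(diff$tested), cfg$diff_fdr)

  ks <- .stage("ksea", suppressMessages(
    ksea(lg, dat$groups, dat$motifs, metric = cfg$metric,
         weight_p = cfg$weight_p, n_perm = cfg$n_perm,
         min_size = cfg$min_size, max_size = cfg$max_size,
         fdr = cfg$ksea_fdr, fdr_relaxed = cfg$ksea_fdr_relaxed,
         seed = cfg$sim$seed + 101L)))
  ks_flat <- dplyr::mutate(as_tibble(ks),
                           leading_edge = vapply(.data$leading_edge, paste,
                                                 character(1), collapse = ","))
  readr::write_tsv(ks_flat, p("ksea.tsv"), na = "")
  note("ksea: %d sets scored, %d at q < %.2f, %d at relaxed q < %.2f",
       nrow(ks), sum(ks$significant), cfg$ksea_fdr,
       sum(ks$relaxed), cfg$ksea_fdr_relaxed)

  status <- .stage("stratification",
                   binarize_quartile(dat$clinical, cfg$kinases, probs = cfg$quartile))
  kh <- k_high(status, cfg$kinases)
  status_out <- dplyr::mutate(status, `K-high` = unname(kh))
  readr::write_tsv(status_out, p("status.tsv"))

  patterns <- .stage("patterns",
                     enumerate_patterns(status, relapse = dat$clinical$event,
                                        kinases = cfg$kinases))
  pat_out <- dplyr::mutate(as_tibble(patterns),
                           n_possible = attr(patterns, "n_possible"))
  readr::write_tsv(pat_out, p("patterns.tsv"))
  note("patterns: %d observed of %d possible",
       attr(patterns, "n_observed"), attr(patterns, "n_possible"))

  screen <- .stage("survival", kinase_screen(dat$clinical, status_out))
  readr::write_tsv(as_tibble(screen), p("survival.tsv"), na = "")
  km <- .stage("km", {
    dd <- dplyr::mutate(dat$clinical, khigh = unname(kh))
    km_fit(dd, group = "khigh")
  })
  readr::write_tsv(km$curve, p("km.tsv"))

  tgi_tbl <- .stage("tgi", {
    arms <- setdiff(unique(dat$growth$arm), "vehicle")
    purrr::map_dfr(arms, function(a) tgi(dat$growth, treated = a,
                                         vehicle = "vehicle"))
  })
  readr::write_tsv(tgi_tbl, p("tgi.tsv"))

  snap <- cfg
  snap$sim <- unclass(snap$sim)
  jsonlite::write_json(unclass(snap), p("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  writeLines(log_lines, p("log.txt"))
  invisible(list(diff = diff, ksea = ks, status = status_out,
                 patterns = patterns, screen = screen, tgi = tgi_tbl,
                 km = km, dir = out_dir))
}
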