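# run `code` under a fixed RNG seed without disturbing the caller's stream
.with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic linear-motif library
#'
#' Builds a library of position-specific linear motifs over a 15-residue window
#' centered on the phosphoresidue: kinase and phosphatase substrate motifs
#' (center constrained to S/T or Y) and SH2-binding motifs (center Y). Each
#' motif constrains one to three flanking positions to small residue sets; all
#' other slots are `"X"` (any residue). Defaults give 327 motifs: 224 kinase,
#' 23 phosphatase, 80 SH2.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with `name`, `category` and slot columns `pos_01`..`pos_15`.
#' @export
#' @examples
#' lib <- simulate_motif_library(sim_config())
#' table(lib$category)
simulate_motif_library <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  counts <- c(kinase = cfg$n_kinase_motifs,
              phosphatase = cfg$n_phosphatase_motifs,
              sh2 = cfg$n_sh2_motifs)
  if (any(counts < 0)) abort("motif counts must be >= 0.")
  prefix <- c(kinase = "KIN", phosphatase = "PHT", sh2 = "SH2")
  .with_seed(cfg$seed + 11L, {
    rows <- purrr::imap_dfr(counts, function(n, cat) {
      if (n == 0L) return(NULL)
      purrr::map_dfr(seq_len(n), function(i) {
        slots <- rep("X", FLANK_LEN)
        # center: SH2 motifs bind phosphotyrosine; kinases/phosphatases mostly S/T
        slots[FLANK_HALF + 1L] <- if (cat == "sh2") "Y" else {
          sample(c("S", "T", "ST", "Y", "STY"), 1,
                 prob = c(0.35, 0.2, 0.3, 0.1, 0.05))
        }
        n_constrained <- sample(1:3, 1)
        at <- sample(setdiff(seq_len(FLANK_LEN), FLANK_HALF + 1L), n_constrained)
        for (j in at) {
          slots[j] <- paste(sample(AA, sample(1:3, 1)), collapse = "")
        }
        out <- as.list(slots)
        names(out) <- sprintf("pos_%02d", seq_len(FLANK_LEN))
        tibble(name = sprintf("%s_%03d", prefix[[cat]], i), category = cat, !!!out)
      })
    })
    if (is.null(rows) || !nrow(rows)) {
      slots <- stats::setNames(rep(list(character()), FLANK_LEN),
                               sprintf("pos_%02d", seq_len(FLANK_LEN)))
      return(tibble(name = character(), category = character(), !!!slots))
    }
    if (anyDuplicated(rows$name)) abort("duplicate motif name generated.")
    rows
  })
}

#' Generate a synthetic proteome with annotated phosphosites
#'
#' Creates random protein sequences and places `n_sites` phosphosites at
#' interior, non-overlapping positions. For every active kinase in `cfg`,
#' `substrates_per_active` sites have their flanking window rewritten to
#' satisfy that kinase's motif, so the true substrate memberships are known by
#' construction. The truth table (`site_id`, `motif`) is returned alongside.
#'
#' @param cfg A [sim_config()].
#' @param motifs Motif library from [simulate_motif_library()].
#' @return List with `proteins` (tibble `protein_id`, `sequence`), `sites`
#'   (tibble `site_id`, `protein_id`, `position`, `residue`, `flank`,
#'   `planted_motif`) and `truth` (planted memberships).
#' @export
simulate_proteome <- function(cfg, motifs) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_sites > 0L && cfg$n_proteins == 0L) {
    abort("cannot place sites: n_proteins is 0.")
  }
  missing_kin <- setdiff(cfg$active_kinases, motifs$name)
  if (length(missing_kin)) {
    abort(sprintf("active kinases not in motif library: %s",
                  paste(missing_kin, collapse = ", ")))
  }
  prot_len <- 120L
  # non-overlapping interior slots, >= 15 residues apart
  slot_pos <- seq(FLANK_HALF + 1L, prot_len - FLANK_HALF, by = FLANK_LEN)
  total_slots <- cfg$n_proteins * length(slot_pos)
  if (cfg$n_sites > total_slots) {
    abort(sprintf("n_sites (%d) exceeds synthesizable positions (%d).",
                  cfg$n_sites, total_slots))
  }
  n_plant <- length(cfg$active_kinases) * cfg$substrates_per_active
  if (n_plant > cfg$n_sites) {
    abort("active kinases require more planted sites than n_sites.")
  }
  .with_seed(cfg$seed + 23L, {
    seqs <- replicate(cfg$n_proteins,
                      paste(sample(AA, prot_len, replace = TRUE), collapse = ""))
    chars <- strsplit(seqs, "", fixed = TRUE)
    slot_df <- tidyr::expand_grid(prot = seq_len(cfg$n_proteins), pos = slot_pos)
    picked <- slot_df[sample(nrow(slot_df), cfg$n_sites), , drop = FALSE]
    picked <- dplyr::arrange(picked, .data$prot, .data$pos)
    planted <- rep(NA_character_, cfg$n_sites)
    if (n_plant > 0L) {
      planted[sample(cfg$n_sites, n_plant)] <-
        rep(cfg$active_kinases, each = cfg$substrates_per_active)
    }
    for (i in seq_len(cfg$n_sites)) {
      p <- picked$prot[i]; pos <- picked$pos[i]
      win_idx <- (pos - FLANK_HALF):(pos + FLANK_HALF)
      if (is.na(planted[i])) {
        chars[[p]][pos] <- sample(c("S", "T", "Y"), 1, prob = c(0.6, 0.25, 0.15))
      } else {
        slots <- .motif_slots(motifs[motifs$name == planted[i], ])
        for (k in seq_len(FLANK_LEN)) {
          pool <- if (slots[k] == "X") AA else strsplit(slots[k], "")[[1]]
          chars[[p]][win_idx[k]] <- if (length(pool) == 1L) pool else sample(pool, 1)
        }
      }
    }
    seqs <- vapply(chars, paste, character(1), collapse = "")
    proteins <- tibble(protein_id = sprintf("PROT_%04d", seq_len(cfg$n_proteins)),
                       sequence = seqs)
    residue <- vapply(seq_len(cfg$n_sites), function(i) {
      substr(seqs[picked$prot[i]], picked$pos[i], picked$pos[i])
    }, character(1))
    flank <- vapply(seq_len(cfg$n_sites), function(i) {
      extract_flank(seqs[picked$prot[i]], picked$pos[i], residue[i])
    }, character(1))
    sites <- tibble(site_id = sprintf("site_%04d", seq_len(cfg$n_sites)),
                    protein_id = proteins$protein_id[picked$prot],
                    position = picked$pos,
                    residue = residue,
                    flank = flank,
                    planted_motif = planted)
    truth <- dplyr::filter(
      tibble(site_id = sites$site_id, motif = planted), !is.na(.data$motif))
    list(proteins = proteins, sites = sites, truth = truth)
  })
}

#' Generate a synthetic phosphosite intensity matrix
#'
#' Log2 intensities are drawn around site-specific baselines with Gaussian
#' noise; substrates of active kinases are shifted upward by `effect_log2fc`
#' in the relapsed group. Dropout is intensity-dependent (logistic in the true
#' log2 intensity, calibrated so the overall missing fraction matches
#' `missing_rate_base`), emulating the lower detection frequency of faint
#' phosphopeptides. Intensities are returned on the raw (linear) scale.
#'
#' @param cfg A [sim_config()] (requires `noise_sd > 0`).
#' @param annotations Site annotation tibble from [simulate_proteome()].
#' @return A site tibble (annotations plus one intensity column per sample)
#'   with attributes `sample_groups` (tibble `sample`, `group`) and `truth`
#'   (logical vector marking planted sites).
#' @export
simulate_site_matrix <- function(cfg, annotations) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$noise_sd <= 0) abort("noise_sd must be > 0 to simulate intensities.")
  n <- nrow(annotations)
  n_per <- cfg$n_samples_per_group
  samples <- c(sprintf("relapsed_%02d", seq_len(n_per)),
               sprintf("nonrelapsed_%02d", seq_len(n_per)))
  groups <- tibble(sample = samples,
                   group = rep(c("relapsed", "non-relapsed"), each = n_per))
  planted <- !is.na(annotations$planted_motif) &
    annotations$planted_motif %in% cfg$active_kinases
  .with_seed(cfg$seed + 37L, {
    base <- rnorm(n, mean = 23, sd = 2)
    mu <- matrix(base, n, 2L * n_per)
    mu[planted, seq_len(n_per)] <- mu[planted, seq_len(n_per)] + cfg$effect_log2fc
    x <- mu + matrix(rnorm(n * 2L * n_per, sd = cfg$noise_sd), n, 2L * n_per)
    if (cfg$missing_rate_base > 0) {
      # logistic MNAR-lite dropout: shift x0 so the mean dropout hits the target
      s <- 2
      f <- function(x0) mean(stats::plogis((x0 - x) / s)) - cfg$missing_rate_base
      x0 <- uniroot(f, lower = min(x) - 50, upper = max(x) + 50)$root
      drop <- matrix(runif(length(x)) < stats::plogis((x0 - x) / s), n, 2L * n_per)
      x[drop] <- NA_real_
    }
    intens <- 2^x
    colnames(intens) <- samples
    out <- dplyr::bind_cols(annotations, as_tibble(intens))
    attr(out, "sample_groups") <- groups
    attr(out, "truth") <- planted
    out
  })
}

#' Generate a synthetic clinical cohort with planted prognostic effects
#'
#' Draws H-scores for the six signature kinases (continuous in `[0,3]`, so
#' roughly 25% of patients exceed each kinase's cohort 75th percentile),
#' standard clinicopathological covariates (T, N, grade, age), and relapse
#' times from an exponential proportional-hazards model in which the hazard is
#' multiplied by the planted hazard ratio whenever the corresponding kinase
#' status (or the derived K-high indicator) is 1. Censoring is independent
#' Uniform(0, c_max), with c_max solved so the expected censored fraction
#' matches `censor_rate`.
#'
#' @param cfg A [sim_config()].
#' @return Tibble with `patient_id`, `T`, `N`, `G`, `age`, `event`, `time`
#'   (months) and one `hs_<kinase>` column per signature kinase. Attribute
#'   `truth` holds the generator's status matrix and K-high indicator.
#' @export
simulate_clinical <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_patients
  .with_seed(cfg$seed + 53L, {
    hs <- vapply(SIGNATURE_KINASES, function(k) 3 * stats::rbeta(n, 2, 3),
                 numeric(n))
    thresholds <- apply(hs, 2, quantile, probs = 0.75, type = 7)
    status <- sweep(hs, 2, thresholds, ">") * 1L
    khigh <- as.integer(rowSums(status) >= 1L)
    log_hr <- rep(0, n)
    for (nm in names(cfg$kinase_hr)) {
      ind <- if (nm == "K-high") khigh else status[, nm]
      log_hr <- log_hr + ind * log(cfg$kinase_hr[[nm]])
    }
    lambda <- cfg$baseline_hazard * exp(log_hr)
    t_event <- rexp(n, rate = lambda)
    if (cfg$censor_rate > 0 && cfg$censor_rate < 1) {
      # P(C < T) for C ~ U(0,c), T ~ Exp(lambda): (1 - (1-exp(-lambda c))/(lambda c))
      pc <- function(cmax) mean(1 - (1 - exp(-lambda * cmax)) / (lambda * cmax))
      cmax <- uniroot(function(cc) pc(cc) - cfg$censor_rate,
                      lower = 1e-6, upper = 1e7)$root
      cens <- runif(n, 0, cmax)
    } else if (cfg$censor_rate >= 1) {
      cens <- runif(n, 0, mean(1 / lambda)) # everything censored below
      t_event <- Inf
    } else {
      cens <- Inf
    }
    event <- as.integer(t_event <= cens)
    time <- pmin(t_event, cens)
    time <- pmax(time, 1e-3) # contract: time > 0
    out <- tibble(patient_id = sprintf("P%03d", seq_len(n)),
                  T = sample(1:4, n, replace = TRUE, prob = c(0.3, 0.4, 0.2, 0.1)),
                  N = sample(0:3, n, replace = TRUE, prob = c(0.5, 0.25, 0.15, 0.1)),
                  G = sample(1:3, n, replace = TRUE, prob = c(0.2, 0.4, 0.4)),
                  age = round(pmin(90, pmax(25, rnorm(n, 56, 11)))),
                  event = event,
                  time = time)
    hs_tbl <- as_tibble(hs)
    names(hs_tbl) <- paste0("hs_", SIGNATURE_KINASES)
    out <- dplyr::bind_cols(out, hs_tbl)
    attr(out, "truth") <- list(status = status, khigh = khigh,
                               thresholds = thresholds)
    out
  })
}

#' Generate synthetic xenograft growth curves
#'
#' Tumor volumes follow `V(t) = V0 * exp(r * m_arm * t)` with multiplicative
#' lognormal measurement noise; `r` is the vehicle growth rate and `m_arm` the
#' per-arm multiplier from `cfg$growth_effect`.
#'
#' @param cfg A [sim_config()].
#' @return Tibble `animal_id`, `arm`, `day`, `volume` (mm^3).
#' @export
simulate_growth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  arms <- names(cfg$growth_effect)
  .with_seed(cfg$seed + 71L, {
    purrr::map_dfr(arms, function(a) {
      mult <- cfg$growth_effect[[a]]
      purrr::map_dfr(seq_len(cfg$n_animals_per_arm), function(i) {
        v0 <- 150
        noise <- if (cfg$growth_noise_sd > 0) {
          rlnorm(length(cfg$growth_days), 0, cfg$growth_noise_sd)
        } else rep(1, length(cfg$growth_days))
        tibble(animal_id = sprintf("%s_%02d", a, i),
               arm = a,
               day = cfg$growth_days,
               volume = v0 * exp(cfg$growth_rate_vehicle * mult * cfg$growth_days) * noise)
      })
    })
  })
}

#' Generate every pipeline input in one call
#'
#' Convenience wrapper running all synthetic-data generators with a shared
#' configuration.
#'
#' @param cfg A [sim_config()].
#' @return List with `motifs`, `proteins`, `sites` (intensity tibble with
#'   group attribute), `groups`, `clinical`, `growth` and `truth`.
#' @export
#' @examples
#' dat <- simulate_cohort(sim_config(n_sites = 50, n_proteins = 20,
#'                                   n_kinase_motifs = 5, n_sh2_motifs = 0,
#'                                   n_phosphatase_motifs = 0, n_patients = 20))
#' names(dat)
simulate_cohort <- function(cfg) {
  motifs <- simulate_motif_library(cfg)
  prot <- simulate_proteome(cfg, motifs)
  sites <- simulate_site_matrix(cfg, prot$sites)
  clinical <- simulate_clinical(cfg)
  growth <- simulate_growth(cfg)
  list(motifs = motifs,
       proteins = prot$proteins,
       sites = sites,
       groups = attr(sites, "sample_groups"),
       clinical = clinical,
       growth = growth,
       truth = list(memberships = prot$truth,
                    planted_sites = attr(sites, "truth"),
                    clinical = attr(clinical, "truth"),
                    seed = cfg$seed))
}
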