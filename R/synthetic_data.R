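# Synthetic study generator.
#
# Emulates a reduced-scale multi-organ 16S survey: per subject, one sample per
# (organ, site, sample type) including paired lumen/mucosa niches, plus
# negative controls. Counts arise from a latent log-space composition model
# (organ base composition, subject-level core-species effects shared across
# the organs of a group, per-organ correlated taxon pairs, lognormal sample
# noise) closed to the simplex, thinned per taxon through a beta-binomial at a
# configured overdispersion. Contaminant taxa are injected into negative
# controls and, at a small carryover rate, into biological samples. Every
# planted effect is recorded in a ground-truth object so each downstream
# stage can be scored without re-reading the configuration.

default_organ_design <- function() {
  list(
    oral_cavity     = list(sites = c("buccal_mucosa", "hard_palate"),
                           types = "surface"),
    esophagus       = list(sites = c("thoracic_part", "cardiac_orifice"),
                           types = "mucosa"),
    stomach         = list(sites = c("fundus", "antrum"),
                           types = c("mucosa", "gastric_juice")),
    small_intestine = list(sites = c("duodenal_bulb", "jejunum", "ileum"),
                           types = c("mucosa", "lumen")),
    large_intestine = list(sites = c("ascending_colon", "transverse_colon",
                                     "sigmoid_colon"),
                           types = c("mucosa", "lumen"))
  )
}

#' Configure a synthetic multi-organ study
#'
#' Builds a fully explicit simulation configuration: taxon identifiers,
#' per-organ base-composition assignments, planted mucosa/lumen enrichment
#' effects, planted contaminants, core species spanning organ groups with a
#' subject-level abundance correlation, and per-organ correlated taxon pairs.
#' The defaults describe a desk-scale version of a dense cadaver survey:
#' 6 subjects, five organs (2-3 sites each), paired lumen/mucosa sampling in
#' stomach, small intestine and large intestine, and 6 negative controls.
#'
#' Taxa fall into four layers: core-species ASVs present in every organ of
#' their group, shared taxa present in every organ (no subject coupling),
#' organ-exclusive taxa (zero base composition elsewhere, which makes
#' false-core scoring exact), and contaminants absent from the biology.
#'
#' @param n_subjects number of subjects.
#' @param organs named list: organ -> list(sites = character, types =
#'   character subset of the sample-type vocabulary). Organs whose types
#'   include mucosa plus lumen or gastric juice are treated as paired.
#' @param n_taxa number of biological taxa (core + shared + organ-exclusive).
#' @param n_controls number of negative controls.
#' @param n_shared_taxa taxa present in all organs without subject coupling.
#' @param library_size_range integer pair; library sizes drawn uniformly.
#' @param rho beta-binomial overdispersion in `[0, 1)`.
#' @param sample_log_sigma sd of lognormal per-sample noise on latent
#'   abundances (0 leaves the beta-binomial as the only overdispersion).
#' @param organ_groups named list of organ sets used for core species.
#' @param core_species optional data frame (species, group, n_asv); defaults
#'   to three species per fully present group with ASV multiplicities 2,1,2.
#' @param core_sd,core_correlation sd of the subject-level log-abundance
#'   effect for core species and its between-organ correlation.
#' @param enrichment_beta,n_enriched_per_organ planted mucosal/luminal
#'   log-odds shift magnitude and number of affected taxa per paired organ
#'   (half mucosa-, half lumen-enriched).
#' @param enrichment_effects optional data frame (taxon, organ, beta_type)
#'   overriding the default placement.
#' @param contaminants list with `n`, `control_prevalence`, `carryover`,
#'   `mean_proportion`.
#' @param network_effects optional data frame (organ, taxon_a, taxon_b,
#'   latent_r); defaults to two organ-exclusive pairs per paired organ at
#'   r = 0.8.
#' @param network_sd sd of the shared latent component realizing pairs.
#' @param core_weight,shared_weight,enriched_weight fixed base-composition
#'   proportions for core ASVs, shared taxa and enriched taxa.
#' @param seed integer seed governing the whole study.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 6,
                       organs = default_organ_design(),
                       n_taxa = 120,
                       n_controls = 6,
                       n_shared_taxa = 20,
                       library_size_range = c(20000L, 40000L),
                       rho = 0.05,
                       sample_log_sigma = 0.6,
                       organ_groups = list(
                         upper_gi = c("esophagus", "stomach"),
                         lower_gi = c("small_intestine", "large_intestine")),
                       core_species = NULL,
                       core_sd = 1,
                       core_correlation = 0.8,
                       enrichment_beta = 2,
                       n_enriched_per_organ = 4,
                       enrichment_effects = NULL,
                       contaminants = list(n = 5, control_prevalence = 0.9,
                                           carryover = 0.05,
                                           mean_proportion = 0.004),
                       network_effects = NULL,
                       network_sd = 1,
                       core_weight = 0.03,
                       shared_weight = 0.012,
                       enriched_weight = 0.004,
                       seed = 1L) {
  stopifnot(n_subjects >= 1, n_taxa >= 1, n_controls >= 0,
            length(library_size_range) == 2,
            library_size_range[1] >= 1,
            library_size_range[2] >= library_size_range[1],
            rho >= 0, rho < 1, sample_log_sigma >= 0,
            core_correlation > 0, core_correlation < 1)
  organ_names <- names(organs)
  if (is.null(organ_names) || any(organ_names == ""))
    stop("organs must be a named list", call. = FALSE)
  bad <- setdiff(organ_names, setdiff(.ORGANS, "negative_control"))
  if (length(bad))
    stop(sprintf("unknown organ(s) in design: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  for (g in names(organ_groups)) {
    missing_org <- setdiff(organ_groups[[g]], organ_names)
    if (length(missing_org) && is.null(core_species)) {
      # default core species only use fully present groups
      organ_groups[[g]] <- NULL
    } else if (length(missing_org)) {
      stop(sprintf("organ group '%s' references organs absent from the design: %s",
                   g, paste(missing_org, collapse = ", ")), call. = FALSE)
    }
  }
  paired_organs <- organ_names[vapply(organs, function(o) {
    "mucosa" %in% o$types && any(c("lumen", "gastric_juice") %in% o$types)
  }, logical(1))]

  if (is.null(core_species)) {
    core_species <- do.call(rbind, lapply(names(organ_groups), function(g) {
      data.frame(species = sprintf("Core_species_%s_%d", g, 1:3),
                 group = g, n_asv = c(2L, 1L, 2L),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(core_species))
      core_species <- data.frame(species = character(), group = character(),
                                 n_asv = integer(), stringsAsFactors = FALSE)
  }
  bad_groups <- setdiff(core_species$group, names(organ_groups))
  if (length(bad_groups))
    stop(sprintf("core species reference unknown organ group(s): %s",
                 paste(unique(bad_groups), collapse = ", ")), call. = FALSE)

  n_core <- sum(core_species$n_asv)
  n_exclusive <- n_taxa - n_core - n_shared_taxa
  if (n_exclusive < length(organ_names))
    stop("n_taxa too small for the configured core/shared layers", call. = FALSE)

  taxa <- sprintf("ASV_%04d", seq_len(n_taxa))
  core_taxa <- if (n_core) taxa[seq_len(n_core)] else character()
  shared_taxa <- if (n_shared_taxa)
    taxa[n_core + seq_len(n_shared_taxa)] else character()
  exclusive_taxa <- taxa[seq.int(n_core + n_shared_taxa + 1, n_taxa)]
  organ_of_exclusive <- rep(organ_names, length.out = n_exclusive)

  core_map <- if (n_core) {
    data.frame(taxon = core_taxa,
               species = rep(core_species$species, core_species$n_asv),
               group = rep(core_species$group, core_species$n_asv),
               stringsAsFactors = FALSE)
  } else {
    data.frame(taxon = character(), species = character(),
               group = character(), stringsAsFactors = FALSE)
  }

  if (is.null(enrichment_effects)) {
    enrichment_effects <- do.call(rbind, lapply(paired_organs, function(o) {
      pool <- exclusive_taxa[organ_of_exclusive == o]
      n_eff <- min(n_enriched_per_organ, length(pool))
      if (!n_eff) return(NULL)
      data.frame(taxon = pool[seq_len(n_eff)], organ = o,
                 beta_type = rep_len(c(enrichment_beta, -enrichment_beta),
                                     n_eff),
                 stringsAsFactors = FALSE)
    }))
    if (is.null(enrichment_effects))
      enrichment_effects <- data.frame(taxon = character(), organ = character(),
                                       beta_type = numeric(),
                                       stringsAsFactors = FALSE)
  }

  if (is.null(network_effects)) {
    network_effects <- do.call(rbind, lapply(paired_organs, function(o) {
      pool <- setdiff(exclusive_taxa[organ_of_exclusive == o],
                      enrichment_effects$taxon)
      if (length(pool) < 4) return(NULL)
      data.frame(organ = o,
                 taxon_a = pool[c(1, 3)], taxon_b = pool[c(2, 4)],
                 latent_r = 0.8, stringsAsFactors = FALSE)
    }))
    if (is.null(network_effects))
      network_effects <- data.frame(organ = character(), taxon_a = character(),
                                    taxon_b = character(), latent_r = numeric(),
                                    stringsAsFactors = FALSE)
  }

  if (nrow(network_effects)) {
    organ_support <- function(taxon, organ) {
      (taxon %in% shared_taxa) ||
        (taxon %in% exclusive_taxa &&
           organ_of_exclusive[match(taxon, exclusive_taxa)] == organ) ||
        (taxon %in% core_map$taxon &&
           organ %in% organ_groups[[core_map$group[match(taxon,
                                                         core_map$taxon)]]])
    }
    for (i in seq_len(nrow(network_effects))) {
      ne <- network_effects[i, ]
      for (t in c(ne$taxon_a, ne$taxon_b)) {
        if (!organ_support(t, ne$organ))
          stop(sprintf(
            "network effect taxon '%s' has no base abundance in organ '%s'",
            t, ne$organ), call. = FALSE)
      }
    }
  }

  contaminant_taxa <- if (contaminants$n > 0)
    sprintf("CONTAM_%02d", seq_len(contaminants$n)) else character()

  structure(list(
    n_subjects = n_subjects, organs = organs, n_taxa = n_taxa,
    n_controls = n_controls, library_size_range = library_size_range,
    rho = rho, sample_log_sigma = sample_log_sigma,
    organ_groups = organ_groups, core_species = core_species,
    core_map = core_map, core_sd = core_sd,
    core_correlation = core_correlation,
    enrichment_effects = enrichment_effects,
    contaminants = contaminants, contaminant_taxa = contaminant_taxa,
    network_effects = network_effects, network_sd = network_sd,
    taxa = taxa, core_taxa = core_taxa, shared_taxa = shared_taxa,
    exclusive_taxa = exclusive_taxa, organ_of_exclusive = organ_of_exclusive,
    core_weight = core_weight, shared_weight = shared_weight,
    enriched_weight = enriched_weight,
    paired_organs = paired_organs, seed = as.integer(seed)),
    class = "sim_config")
}

# Per-organ base composition on the simplex. Core and shared taxa get fixed
# mass; organ-exclusive taxa split the remainder with lognormal weights.
build_base_composition <- function(cfg) {
  all_taxa <- c(cfg$taxa, cfg$contaminant_taxa)
  W <- matrix(0, nrow = length(all_taxa), ncol = length(cfg$organs),
              dimnames = list(all_taxa, names(cfg$organs)))
  for (o in names(cfg$organs)) {
    w <- stats::setNames(numeric(length(all_taxa)), all_taxa)
    if (nrow(cfg$core_map)) {
      in_group <- vapply(cfg$core_map$group,
                         function(g) o %in% cfg$organ_groups[[g]], logical(1))
      w[cfg$core_map$taxon[in_group]] <- cfg$core_weight
    }
    w[cfg$shared_taxa] <- cfg$shared_weight
    excl <- cfg$exclusive_taxa[cfg$organ_of_exclusive == o]
    if (length(excl)) {
      enriched <- intersect(excl, cfg$enrichment_effects$taxon)
      rest <- setdiff(excl, enriched)
      # mass balance: for small w, a +beta logit shift adds ~w (e^beta - 1)
      # while a -beta shift removes ~w (1 - e^-beta); giving lumen-enriched
      # taxa e^|beta| times the weight keeps the mucosal composition total
      # (hence the other taxa's effective shifts) unperturbed to first order
      if (length(enriched)) {
        betas <- cfg$enrichment_effects$beta_type[
          match(enriched, cfg$enrichment_effects$taxon)]
        w[enriched] <- ifelse(betas >= 0, cfg$enriched_weight,
                              cfg$enriched_weight * exp(abs(betas)))
      }
      budget <- max(1 - sum(w), 0.2)
      if (length(rest)) {
        raw <- stats::rlnorm(length(rest), 0, 1)
        w[rest] <- budget * raw / sum(raw)
      }
    }
    W[, o] <- w / sum(w)
  }
  W
}

softmax_from_log <- function(w) {
  w <- w - max(w)
  e <- exp(w)
  e / sum(e)
}

#' Generate a synthetic study with ground truth
#'
#' Realizes the configured design: per subject one sample per (organ, site,
#' sample type), plus negative controls. See [sim_config()] for the model.
#'
#' @param config a `sim_config`.
#' @param keep_latent if TRUE, store the latent per-sample proportions in the
#'   ground truth (memory permitting).
#' @return list with elements `bundle` (a `study_bundle`) and `truth` (planted
#'   effects: `enrichment`, `contaminants`, `core`, `shared_taxa`, `network`,
#'   `base_composition`, optionally `latent`).
#' @export
generate_study <- function(config, keep_latent = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    all_taxa <- c(cfg$taxa, cfg$contaminant_taxa)
    D <- length(all_taxa)
    W <- build_base_composition(cfg)

    subjects <- sprintf("sub%02d", seq_len(cfg$n_subjects))
    covars <- data.frame(
      subject_id = subjects,
      age = round(stats::runif(cfg$n_subjects, 25, 70)),
      sex = sample(c("male", "female"), cfg$n_subjects, replace = TRUE),
      BMI = round(stats::rnorm(cfg$n_subjects, 23, 3), 1),
      antibiotics = stats::rbinom(cfg$n_subjects, 1, 0.3),
      hospitalization_days = stats::rpois(cfg$n_subjects, 5),
      stringsAsFactors = FALSE)

    species <- unique(cfg$core_map$species)
    u <- matrix(stats::rnorm(cfg$n_subjects * length(species)),
                nrow = cfg$n_subjects,
                dimnames = list(subjects, species))
    organ_names <- names(cfg$organs)
    v <- array(stats::rnorm(cfg$n_subjects * length(organ_names) *
                              length(species)),
               dim = c(cfg$n_subjects, length(organ_names), length(species)),
               dimnames = list(subjects, organ_names, species))

    meta <- list(); cols <- list(); latent <- list()
    r <- cfg$core_correlation
    ls_lo <- cfg$library_size_range[1]; ls_hi <- cfg$library_size_range[2]

    for (i in seq_along(subjects)) {
      for (o in organ_names) {
        base_log <- ifelse(W[, o] > 0, log(W[, o]), -Inf)
        support <- which(W[, o] > 0)
        eff <- cfg$enrichment_effects[cfg$enrichment_effects$organ == o, ,
                                      drop = FALSE]
        net <- cfg$network_effects[cfg$network_effects$organ == o, ,
                                   drop = FALSE]
        core_here <- cfg$core_map[vapply(cfg$core_map$group, function(g)
          o %in% cfg$organ_groups[[g]], logical(1)), , drop = FALSE]
        for (site in cfg$organs[[o]]$sites) {
          for (type in cfg$organs[[o]]$types) {
            w <- base_log
            if (nrow(core_here)) {
              shift <- cfg$core_sd *
                (sqrt(r) * u[i, core_here$species] +
                   sqrt(1 - r) * v[i, o, core_here$species])
              w[core_here$taxon] <- w[core_here$taxon] + shift
            }
            if (nrow(net)) {
              e1 <- stats::rnorm(nrow(net)); e2 <- stats::rnorm(nrow(net))
              z2 <- net$latent_r * e1 + sqrt(1 - net$latent_r^2) * e2
              w[net$taxon_a] <- w[net$taxon_a] + cfg$network_sd * e1
              w[net$taxon_b] <- w[net$taxon_b] + cfg$network_sd * z2
            }
            w[support] <- w[support] +
              stats::rnorm(length(support), 0, cfg$sample_log_sigma)
            p <- numeric(D)
            p[support] <- softmax_from_log(w[support])
            if (type == "mucosa" && nrow(eff)) {
              idx <- match(eff$taxon, all_taxa)
              p[idx] <- stats::plogis(stats::qlogis(p[idx]) + eff$beta_type)
              p <- p / sum(p)
            }
            N <- if (ls_lo == ls_hi) ls_lo else
              sample(seq.int(ls_lo, ls_hi), 1)
            y <- numeric(D)
            ps <- p[support]
            if (cfg$rho > 0) {
              a <- ps * (1 - cfg$rho) / cfg$rho
              b <- (1 - ps) * (1 - cfg$rho) / cfg$rho
              pd <- stats::rbeta(length(ps), a, b)
              y[support] <- stats::rbinom(length(ps), N, pd)
            } else {
              y[support] <- stats::rbinom(length(ps), N, ps)
            }
            # reagent carryover into biological samples
            n_cont <- length(cfg$contaminant_taxa)
            if (n_cont) {
              hit <- stats::runif(n_cont) < cfg$contaminants$carryover
              if (any(hit)) {
                q <- pmin(stats::rlnorm(sum(hit),
                                        log(cfg$contaminants$mean_proportion),
                                        0.5), 0.05)
                y[match(cfg$contaminant_taxa[hit], all_taxa)] <-
                  stats::rbinom(sum(hit), N, q)
              }
            }
            sid <- sprintf("%s_%s_%s_%s", subjects[i], o, site, type)
            meta[[sid]] <- data.frame(
              sample_id = sid, subject_id = subjects[i], organ = o,
              site = site, sample_type = type, stringsAsFactors = FALSE)
            cols[[sid]] <- y
            if (keep_latent) latent[[sid]] <- p
          }
        }
      }
    }

    # negative controls: contaminants only
    if (cfg$n_controls > 0) {
      n_cont <- length(cfg$contaminant_taxa)
      for (k in seq_len(cfg$n_controls)) {
        sid <- sprintf("ctrl%02d", k)
        y <- numeric(D)
        if (n_cont) {
          present <- stats::runif(n_cont) < cfg$contaminants$control_prevalence
          if (any(present)) {
            pr <- stats::rgamma(sum(present), 2)
            pr <- pr / sum(pr)
            N <- if (ls_lo == ls_hi) ls_lo else sample(seq.int(ls_lo, ls_hi), 1)
            y[match(cfg$contaminant_taxa[present], all_taxa)] <-
              stats::rmultinom(1, N, pr)[, 1]
          }
        }
        meta[[sid]] <- data.frame(
          sample_id = sid, subject_id = sid, organ = "negative_control",
          site = "control", sample_type = "control", stringsAsFactors = FALSE)
        cols[[sid]] <- y
      }
    }

    m <- do.call(cbind, cols)
    rownames(m) <- all_taxa
    meta_df <- do.call(rbind, meta)
    meta_df <- merge(meta_df, covars, by = "subject_id", all.x = TRUE,
                     sort = FALSE)
    meta_df <- meta_df[match(colnames(m), meta_df$sample_id),
                       c("sample_id", "subject_id", "organ", "site",
                         "sample_type", "age", "sex", "BMI", "antibiotics",
                         "hospitalization_days")]

    taxonomy <- build_sim_taxonomy(cfg)
    tree <- if (D >= 2) {
      tr <- ape::rcoal(D, tip.label = sample(all_taxa))
      tr
    } else NULL

    bundle <- suppressWarnings(assemble_bundle(
      count_table(m), sample_table(meta_df), taxonomy, tree))

    truth <- list(
      enrichment = cfg$enrichment_effects,
      contaminants = cfg$contaminant_taxa,
      core = cfg$core_map,
      core_correlation = cfg$core_correlation,
      shared_taxa = cfg$shared_taxa,
      network = cfg$network_effects,
      rho = cfg$rho,
      base_composition = W,
      organ_groups = cfg$organ_groups)
    if (keep_latent) truth$latent <- do.call(cbind, latent)
    list(bundle = bundle, truth = truth)
  })
}

# Taxonomy for simulated taxa: core ASVs share a species within their planted
# group; shared and exclusive taxa get their own species, except a tail of
# exclusive taxa left unclassified at species rank to exercise the
# pseudo-species path. Contaminants get environmental-style genera.
build_sim_taxonomy <- function(cfg) {
  all_taxa <- c(cfg$taxa, cfg$contaminant_taxa)
  phyla <- c("Proteobacteria", "Firmicutes", "Bacteroidetes",
             "Actinobacteria", "Fusobacteria", "Tenericutes")
  df <- data.frame(taxon_id = all_taxa, stringsAsFactors = FALSE)
  df$kingdom <- "Bacteria"
  # consistent hierarchy: ~3 ASVs per genus, 3 genera per family,
  # families cycle over phyla
  genus_idx <- (seq_along(all_taxa) - 1) %/% 3
  family_idx <- genus_idx %/% 3
  df$phylum <- phyla[family_idx %% length(phyla) + 1]
  df$class <- paste0("Class_", df$phylum)
  df$order <- paste0("Order_", df$phylum)
  df$family <- sprintf("Family_%02d", family_idx + 1)
  df$genus <- sprintf("Genus_%03d", genus_idx + 1)
  df$species <- sprintf("Species_%04d", seq_along(all_taxa))
  idx_core <- match(cfg$core_map$taxon, all_taxa)
  if (length(idx_core)) {
    df$species[idx_core] <- cfg$core_map$species
    df$genus[idx_core] <- paste0("Genus_", cfg$core_map$species)
    df$family[idx_core] <- paste0("Family_", cfg$core_map$group)
    df$phylum[idx_core] <- "Firmicutes"
    df$class[idx_core] <- "Class_Firmicutes"
    df$order[idx_core] <- "Order_Firmicutes"
  }
  # last 10% of exclusive taxa: unclassified at species (and genus) rank
  n_uncl <- max(1L, length(cfg$exclusive_taxa) %/% 10)
  idx_uncl <- match(utils::tail(cfg$exclusive_taxa, n_uncl), all_taxa)
  df$species[idx_uncl] <- ""
  if (length(cfg$contaminant_taxa)) {
    idx_cont <- match(cfg$contaminant_taxa, all_taxa)
    df$genus[idx_cont] <- sprintf("EnvGenus_%02d", seq_along(idx_cont))
    df$species[idx_cont] <- sprintf("Env_species_%02d", seq_along(idx_cont))
  }
  taxonomy_table(df)
}

#' Write a simulated study to disk
#'
#' Writes `counts.tsv`, `meta.tsv`, `taxonomy.tsv`, `tree.nwk` and
#' `truth.json` into a directory.
#'
#' @param study result of [generate_study()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  b <- study$bundle
  write_count_table(b$counts, file.path(dir, "counts.tsv"))
  write_sample_table(b$samples, file.path(dir, "meta.tsv"))
  if (!is.null(b$taxonomy))
    write_taxonomy_table(b$taxonomy, file.path(dir, "taxonomy.tsv"))
  if (!is.null(b$tree))
    ape::write.tree(b$tree, file.path(dir, "tree.nwk"))
  truth <- study$truth
  truth$base_composition <- NULL  # large; reproducible from the config seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
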