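# Config-driven orchestration: simulate (or load) replicate trajectories,
# run the selected analyses, and write a machine-readable report bundle.

.TOP_KEYS <- c("synthetic", "inputs", "sites", "thresholds", "analyses",
               "seed", "report_decimals", "n_components", "cluster",
               "trim", "output_dir")
.ANALYSES <- c("extrahelicity", "ejection", "bend", "contacts", "cluster",
               "pca")

#' Site specification for a builder duplex
#'
#' Convenience constructor of a [site_spec()] for structures from
#' [build_bdna()]: the facing residue of strand-I residue `i` is `2n+1-i`
#' on strand J, and the section spans the whole duplex.
#'
#' @param structure a built duplex (needs `$meta$n_bp`).
#' @param lesion_resno lesion residue number on strand I.
#' @param orphan_resno optional orphan-base residue number (strand J
#'   numbering, `n+1..2n`).
#' @param label,replicate labels passed through.
#' @export
duplex_site_spec <- function(structure, lesion_resno, orphan_resno = NULL,
                             label = "site", replicate = "MD1") {
  n <- structure$meta$n_bp
  if (is.null(n)) .stopf("structure lacks builder metadata")
  orphan <- NULL; orphan_partner <- NULL
  if (!is.null(orphan_resno)) {
    orphan <- list(chain = "J", resno = orphan_resno)
    orphan_partner <- list(chain = "I", resno = 2 * n + 1 - orphan_resno)
  }
  site_spec(lesion = list(chain = "I", resno = lesion_resno),
            facing = list(chain = "J", resno = 2 * n + 1 - lesion_resno),
            orphan = orphan, orphan_partner = orphan_partner,
            section_i = list(chain = "I", from = 1, to = n),
            section_j = list(chain = "J", from = n + 1, to = 2 * n),
            label = label, replicate = replicate)
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes an equivalent list), checks it against the
#' schema, rejects unknown keys and fills defaults: thresholds 14/10/6
#' Angstrom, 10 principal components, 1 report decimal, section trim 1,
#' cluster cut 2.5 Angstrom, all analyses.
#'
#' @param config path to a YAML file or a list.
#' @return a validated `run_config` list.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) .stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), .TOP_KEYS)
  if (length(unknown))
    .stopf("unknown config keys: %s", paste(unknown, collapse = ", "))
  has_syn <- !is.null(config$synthetic)
  has_inp <- !is.null(config$inputs)
  if (has_syn == has_inp)
    .stopf("exactly one of 'synthetic' or 'inputs' must be present")
  th <- config$thresholds
  cfg_th <- threshold_config(
    extrahelical_c1p_threshold = th$extrahelical %||% 14,
    ejection_com_threshold = th$ejection %||% 10,
    canonical_com_reference = th$canonical_reference %||% 6.8,
    contact_cutoff = th$contact %||% 6)
  analyses <- config$analyses %||% .ANALYSES
  bad <- setdiff(analyses, .ANALYSES)
  if (length(bad)) .stopf("unknown analyses: %s", paste(bad, collapse = ", "))
  if (has_syn) {
    syn <- config$synthetic
    need <- c("sequence", "lesion", "replicates")
    miss <- setdiff(need, names(syn))
    if (length(miss))
      .stopf("synthetic block misses fields: %s", paste(miss, collapse = ", "))
    if (is.null(syn$lesion$position))
      .stopf("synthetic lesion needs a 'position'")
    for (r in syn$replicates)
      if (is.null(r$label) || is.null(r$extrahelical_fraction))
        .stopf("every replicate needs 'label' and 'extrahelical_fraction'")
  } else {
    inp <- config$inputs
    if (is.null(inp$topology) || is.null(inp$replicates))
      .stopf("inputs block needs 'topology' and 'replicates'")
    paths <- c(inp$topology,
               vapply(inp$replicates, function(r) r$trajectory, ""))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      .stopf("input file(s) not found: %s", paste(missing, collapse = ", "))
    if (is.null(config$sites))
      .stopf("inputs mode requires a 'sites' block")
  }
  structure(list(synthetic = config$synthetic, inputs = config$inputs,
                 sites = config$sites, thresholds = cfg_th,
                 analyses = analyses, seed = config$seed %||% 1L,
                 report_decimals = config$report_decimals %||% 1L,
                 n_components = config$n_components %||% 10L,
                 cluster = list(eps = config$cluster$eps %||% 2.5,
                                k = config$cluster$k,
                                max_frames = config$cluster$max_frames %||%
                                  200L),
                 trim = config$trim %||% 1L,
                 output_dir = config$output_dir),
            class = "run_config")
}

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
.log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

# Build one synthetic replicate trajectory from the config.
#' @noRd
.synthetic_replicate <- function(cfg, rep_cfg, rep_index) {
  syn <- cfg$synthetic
  sc <- synth_config(syn$sequence,
                     lesion_position = syn$lesion$position,
                     lesion_type = syn$lesion$type %||% "AP")
  st <- build_bdna(sc)
  if (!is.null(syn$bend_angle) && syn$bend_angle > 0)
    st <- bend_arc(st, syn$bend_angle)
  n <- st$meta$n_bp
  flips <- list(flip_spec(syn$lesion$position, chain = "I", name = "lesion",
                          mode = "exact_fraction",
                          fraction = rep_cfg$extrahelical_fraction))
  if (!is.null(syn$orphan)) {
    orp <- rep_cfg$ejection_fraction %||% rep_cfg$extrahelical_fraction
    flips[[2]] <- flip_spec(syn$orphan$position, chain = "J",
                            name = "orphan", mode = "exact_fraction",
                            fraction = orp)
  }
  seed_rep <- as.integer(cfg$seed) + rep_index - 1L
  tr <- simulate_flip_dynamics(st, flips,
                               n_frames = syn$n_frames %||% 500L,
                               seed = seed_rep,
                               noise_sigma = syn$noise_sigma %||% 0.1)
  if (!is.null(syn$contact)) {
    ep <- do.call(rbind, lapply(syn$contact$episodes, as.data.frame))
    script <- contact_script(ep,
                             off_distance = syn$contact$off_distance %||% 20)
    tr <- add_tail_probe(tr, script, site_resno = syn$lesion$position,
                         site_chain = "I")
  }
  tr
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the replicate trajectories and computes the
#' selected analyses. Deterministic for a given config and seed.
#'
#' @param cfg a `run_config` from [validate_config()].
#' @param verbose log one line per stage to standard error.
#' @return a `report_bundle` list with elements among `extrahelicity`,
#'   `ejection`, `bend`, `contacts`, `cluster`, `importance`, plus
#'   `provenance`.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  bundle <- list()
  if (!is.null(cfg$synthetic)) {
    syn <- cfg$synthetic
    reps <- lapply(seq_along(syn$replicates), function(i)
      .synthetic_replicate(cfg, syn$replicates[[i]], i))
    names(reps) <- vapply(syn$replicates, function(r) r$label, "")
    st0 <- reps[[1]]$topology
    spec <- duplex_site_spec(st0, syn$lesion$position,
                             orphan_resno = syn$orphan$position %||% NULL,
                             label = "site")
  } else {
    topo <- read_structure(cfg$inputs$topology)
    reps <- lapply(cfg$inputs$replicates, function(r)
      read_trajectory(r$trajectory, topo))
    names(reps) <- vapply(cfg$inputs$replicates, function(r) r$label, "")
    s <- cfg$sites[[1]]
    spec <- site_spec(lesion = s$lesion, facing = s$facing,
                      orphan = s$orphan, orphan_partner = s$orphan_partner,
                      section_i = s$section_i, section_j = s$section_j,
                      label = s$label %||% "site")
  }
  .log_stage(verbose, "loaded %d replicate(s), %d frames each",
             length(reps), reps[[1]]$n_frames)
  dec <- cfg$report_decimals
  if ("extrahelicity" %in% cfg$analyses) {
    p <- vapply(reps, function(tr)
      extrahelicity_percent(c1p_distance_series(tr, spec),
                            cfg$thresholds), 0)
    bundle$extrahelicity <- aggregate_replicates(p, dec)
    .log_stage(verbose, "extrahelicity: all %.1f%%",
               bundle$extrahelicity$all_mean)
  }
  if ("ejection" %in% cfg$analyses && !is.null(spec$orphan)) {
    p <- vapply(reps, function(tr)
      ejection_fraction(com_distance_series(tr, spec$orphan,
                                            spec$orphan_partner),
                        cfg$thresholds), 0)
    bundle$ejection <- aggregate_replicates(p, dec)
    .log_stage(verbose, "ejection: all %.1f%%", bundle$ejection$all_mean)
  }
  if ("bend" %in% cfg$analyses) {
    ang <- lapply(reps, function(tr) bend_angle_series(tr, spec))
    bundle$bend <- data.frame(
      replicate = names(reps),
      mean = vapply(ang, function(a) a$mean, 0),
      std = vapply(ang, function(a) ifelse(is.na(a$std), 0, a$std), 0),
      row.names = NULL)
    .log_stage(verbose, "bend angle: %.1f degrees (first replicate)",
               bundle$bend$mean[1])
  }
  if ("contacts" %in% cfg$analyses) {
    has_probe <- vapply(reps, function(tr)
      any(tr$topology$atoms$chain == "P"), TRUE)
    if (all(has_probe)) {
      site_idx <- select_atoms(reps[[1]]$topology,
                               chain = spec$lesion$chain,
                               resno = spec$lesion$resno, heavy = TRUE)
      groups <- find_charged_groups(reps[[1]]$topology, "P")
      pairs <- lapply(groups, function(g) list(
        label = sprintf("%s %s:%d-%s%d", g$kind, g$chain, g$resno,
                        "site", spec$lesion$resno),
        group = g, site_idx = site_idx))
      bundle$contacts <- contact_table(reps, pairs,
                                       cutoff =
                                         cfg$thresholds$contact_cutoff,
                                       decimals = dec)
      .log_stage(verbose, "contacts: %d pair(s)", length(bundle$contacts))
    }
  }
  if ("cluster" %in% cfg$analyses || "pca" %in% cfg$analyses) {
    sections <- lapply(reps, extract_section, spec = spec, trim = cfg$trim)
    if ("cluster" %in% cfg$analyses) {
      bundle$cluster <- lapply(sections, function(sec) {
        keep <- seq_len(sec$n_frames)
        if (sec$n_frames > cfg$cluster$max_frames)
          keep <- round(seq(1, sec$n_frames,
                            length.out = cfg$cluster$max_frames))
        sub <- ncp_trajectory(sec$topology,
                              sec$coords[, , keep, drop = FALSE])
        cluster_frames(pairwise_rmsd(sub), eps = cfg$cluster$eps,
                       k = cfg$cluster$k)
      })
      .log_stage(verbose, "cluster: %d cluster(s) in first replicate",
                 length(bundle$cluster[[1]]$occupancy))
    }
    if ("pca" %in% cfg$analyses) {
      sec <- sections[[1]]
      pf <- pair_features(sec)
      bundle$importance <- residue_importance(
        pca_fit(pf), n_components = cfg$n_components)
      .log_stage(verbose, "pca: %d residues scored",
                 nrow(bundle$importance$per_residue))
    }
  }
  bundle$provenance <- list(
    seed = cfg$seed, analyses = cfg$analyses,
    thresholds = unclass(cfg$thresholds),
    config_hash = .config_hash(cfg),
    package_version = as.character(utils::packageVersion("ncptraj")))
  class(bundle) <- "report_bundle"
  bundle
}

#' @noRd
.config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(unclass(cfg)[sort(names(unclass(cfg)))], f)
  # md5 of the canonicalized config serialization
  unname(tools::md5sum(f))
}

#' Write a report bundle to disk
#'
#' CSV tables (occupancy-table layout for extrahelicity/ejection/contacts,
#' cluster occupancies, importance map) plus a JSON mirror of the whole
#' bundle. Every file header carries the config hash.
#'
#' @param bundle a `report_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- sprintf("# config_hash: %s", bundle$provenance$config_hash)
  put <- function(df, name) {
    path <- file.path(dir, name)
    writeLines(stamp, path)
    suppressWarnings(utils::write.table(df, path, append = TRUE, sep = ",",
                                        row.names = FALSE, quote = FALSE))
    path
  }
  if (!is.null(bundle$extrahelicity))
    put(occupancy_table(list(extrahelicity = bundle$extrahelicity)),
        "extrahelicity.csv")
  if (!is.null(bundle$ejection))
    put(occupancy_table(list(ejection = bundle$ejection)), "ejection.csv")
  if (!is.null(bundle$bend)) put(bundle$bend, "bend_angle.csv")
  if (!is.null(bundle$contacts)) {
    rows <- stats::setNames(lapply(bundle$contacts, function(x) x$summary),
                            vapply(bundle$contacts,
                                   function(x) x$pair_label, ""))
    put(occupancy_table(rows), "contacts.csv")
  }
  if (!is.null(bundle$cluster)) {
    df <- do.call(rbind, lapply(names(bundle$cluster), function(nm) {
      cl <- bundle$cluster[[nm]]
      data.frame(replicate = nm, cluster = names(cl$occupancy),
                 occupancy = round_half_up(cl$occupancy, 1),
                 medoid = cl$medoid, row.names = NULL)
    }))
    put(df, "clusters.csv")
  }
  if (!is.null(bundle$importance))
    put(bundle$importance$per_residue, "importance.csv")
  json <- jsonlite::toJSON(.bundle_as_list(bundle), auto_unbox = TRUE,
                           digits = NA, pretty = TRUE)
  writeLines(json, file.path(dir, "bundle.json"))
  invisible(dir)
}

#' @noRd
.bundle_as_list <- function(bundle) {
  out <- list()
  pct <- function(s) list(per_replicate = as.list(s$per_replicate),
                          all_mean = s$all_mean, all_std = s$all_std)
  if (!is.null(bundle$extrahelicity))
    out$extrahelicity <- pct(bundle$extrahelicity)
  if (!is.null(bundle$ejection)) out$ejection <- pct(bundle$ejection)
  if (!is.null(bundle$bend)) out$bend <- bundle$bend
  if (!is.null(bundle$contacts))
    out$contacts <- lapply(bundle$contacts, function(x)
      c(list(pair = x$pair_label), pct(x$summary)))
  if (!is.null(bundle$cluster))
    out$cluster <- lapply(bundle$cluster, function(cl)
      list(occupancy = as.list(cl$occupancy),
           medoid = as.list(cl$medoid)))
  if (!is.null(bundle$importance))
    out$importance <- bundle$importance$per_residue
  out$provenance <- bundle$provenance
  out
}
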