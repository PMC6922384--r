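#' Run the full structural fingerprint analysis
#'
#' Orchestrates the whole comparative pipeline over a set of domains:
#' pairwise RMSD/identity matrices, per-residue deviation profiles with
#' hotspot calls, sheet topology and cross-structure hydrogen-bond
#' conservation, cysteine accessibility reports with disulfide and
#' metal-site detection, a domain summary (pI, cysteine counts), the master
#' structure-based alignment with conservation categories, and, when a
#' variant table is supplied, structural variant annotation. Stages without
#' inputs are skipped; all outputs are plain TSV/JSON and two runs with the
#' same config are byte-identical.
#'
#' @param config A list (or path to a JSON file) with entries:
#'   `registry` (path to a domain-registry TSV, see [read_registry()]) or
#'   `domains` (a named list of `domain_structure` objects), optional
#'   `reference` (deviation-profile/master-alignment reference label,
#'   default the last domain), optional `species_panel` (named list as in
#'   [classify_columns()]), optional `variants` (path to a variant TSV),
#'   and optional parameter overrides `trim_cutoff`, `hotspot_threshold`,
#'   `exposure_threshold`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a `fingerprint_report` list with every stage result.
#' @export
run_fingerprint <- function(config, out_dir) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) {
    log <<- c(log, paste0(...))
  }
  domains <- config$domains
  if (is.null(domains)) {
    if (is.null(config$registry)) stop("config needs 'registry' or 'domains'")
    reg <- read_registry(config$registry)
    domains <- load_registry_domains(reg)
  }
  trim <- config$trim_cutoff %||% 4.5
  hotspot <- config$hotspot_threshold %||% 4
  expo <- config$exposure_threshold %||% 5
  reference <- config$reference %||% names(domains)[length(domains)]
  say("stage=load n_domains=", length(domains),
      " reference=", reference, " trim_cutoff=", trim,
      " hotspot_threshold=", hotspot, " exposure_threshold=", expo)
  report <- list(config = config, reference = reference)

  mats <- pairwise_rmsd_matrix(domains, trim_cutoff = trim)
  report$rmsd <- mats$rmsd
  report$identity <- mats$identity
  write_matrix_tsv(mats$rmsd, mats$identity,
                   file.path(out_dir, "rmsd_identity_matrix.tsv"))
  say("stage=superpose pairs=", sum(!is.na(mats$rmsd[upper.tri(mats$rmsd)])),
      " failures=", length(mats$failures))

  others <- domains[setdiff(names(domains), reference)]
  report$profiles <- deviation_profile(domains[[reference]], others,
                                       hotspot_threshold = hotspot,
                                       trim_cutoff = trim)
  prof_df <- do.call(rbind, lapply(names(report$profiles), function(lab) {
    cbind(domain = lab, report$profiles[[lab]])
  }))
  write_tsv(prof_df, file.path(out_dir, "deviation_profiles.tsv"))
  say("stage=profiles hotspots=", sum(prof_df$hotspot))

  report$topology <- lapply(domains, assign_topology)
  topo_df <- do.call(rbind, lapply(names(domains), function(lab) {
    cbind(domain = lab, report$topology[[lab]]$residues)
  }))
  write_tsv(topo_df, file.path(out_dir, "topology.tsv"))
  say("stage=topology strands=",
      paste(vapply(report$topology, function(t) nrow(t$strands), numeric(1)),
            collapse = ","))

  report$master <- build_master_alignment(domains, reference = reference,
                                          trim_cutoff = trim)
  writeLines(
    unlist(lapply(names(master_alignment_fasta(report$master)), function(n) {
      c(paste0(">", n), master_alignment_fasta(report$master)[[n]])
    })),
    file.path(out_dir, "master_alignment.fasta"))
  report$conservation <- classify_columns(report$master,
                                          panel = config$species_panel)
  write_tsv(report$conservation$columns,
            file.path(out_dir, "conservation_columns.tsv"))
  say("stage=conservation ",
      paste(names(report$conservation$counts),
            as.integer(report$conservation$counts),
            sep = "=", collapse = " "))

  report$hbond_conservation <- hbond_conservation(domains, report$master)
  write_tsv(report$hbond_conservation$table,
            file.path(out_dir, "hbond_conservation.tsv"))
  say("stage=hbonds per_sheet=",
      paste(names(report$hbond_conservation$per_sheet),
            report$hbond_conservation$per_sheet, sep = "=", collapse = " "))

  cys <- lapply(domains, classify_cysteines, exposure_threshold = expo)
  report$cysteines <- cys
  cys_df <- do.call(rbind, lapply(names(cys), function(lab) {
    r <- cys[[lab]]$report
    if (nrow(r) == 0) return(NULL)
    cbind(domain = lab, r[, c("local_index", "sidechain_asa",
                              "relative_accessibility", "class",
                              "partner", "sg_sg_distance")])
  }))
  if (!is.null(cys_df)) {
    write_tsv(cys_df, file.path(out_dir, "cysteine_report.tsv"))
  }
  report$summary <- data.frame(
    domain = names(domains),
    pdb_id = vapply(domains, function(d) d$pdb_id, character(1)),
    pI = vapply(domains, function(d) isoelectric_point(domain_sequence(d)),
                numeric(1)),
    n_cys_total = vapply(cys, function(x) x$n_total, integer(1)),
    n_cys_accessible = vapply(cys, function(x) x$n_accessible, integer(1)),
    stringsAsFactors = FALSE
  )
  write_tsv(report$summary, file.path(out_dir, "domain_summary.tsv"))
  say("stage=redox cys_total=", sum(report$summary$n_cys_total),
      " cys_accessible=", sum(report$summary$n_cys_accessible))

  if (!is.null(config$variants)) {
    variants <- read_variants(config$variants)
    reg_len <- data.frame(
      domain = names(domains),
      offset = vapply(domains, function(d) d$numbering$offset, integer(1)),
      length = vapply(domains, n_residues, integer(1))
    )
    report$variants <- annotate_variants(variants, reg_len, domains)
    write_tsv(report$variants, file.path(out_dir, "variant_annotation.tsv"))
    say("stage=variants n=", nrow(report$variants))
  }

  meta <- list(
    package = "mbandIg",
    version = as.character(utils::packageVersion("mbandIg")),
    reference = reference,
    parameters = list(trim_cutoff = trim, hotspot_threshold = hotspot,
                      exposure_threshold = expo),
    domains = names(domains)
  )
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  writeLines(log, file.path(out_dir, "run_log.txt"))
  class(report) <- "fingerprint_report"
  invisible(report)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

## Table layout mirroring the comparative table: lower triangle RMSD (Å),
## upper triangle structure-based identity (%).
write_matrix_tsv <- function(rmsd, identity, path) {
  m <- matrix("", nrow(rmsd), ncol(rmsd), dimnames = dimnames(rmsd))
  m[lower.tri(m)] <- sprintf("%.2f", rmsd[lower.tri(rmsd)])
  m[upper.tri(m)] <- sprintf("%.1f", identity[upper.tri(identity)])
  df <- data.frame(domain = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}
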