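## conservative-substitution classes for the impact rule; cysteine groups
## with the small polar residues here because C->S-type swaps preserve the
## side-chain envelope in a packed core
IMPACT_CONSERVATIVE_GROUPS <- list(c("I", "L", "V", "M"), c("F", "Y", "W"),
                                   c("K", "R"), c("D", "E"),
                                   c("S", "T", "C"))

#' Default thresholds of the variant-impact rule set
#'
#' @return List: `core_rel_asa` (relative accessibility below which a site
#'   counts as hydrophobic core, %), `destab_cutoff` (stability change at or
#'   below which a core mutation counts as destabilizing, kcal/mol),
#'   `conservative_groups` (substitution classes exempt from the core rule).
#' @export
impact_rules <- function() {
  list(core_rel_asa = 10,
       destab_cutoff = -1.3,
       conservative_groups = IMPACT_CONSERVATIVE_GROUPS)
}

#' Map a full-titin missense position onto a domain
#'
#' @param uniprot_position Position in the full-length titin sequence.
#' @param wt,mut Single-letter wild-type and mutant residues.
#' @param registry Data frame with columns `domain`, `offset`, `length`
#'   (domain length in residues); the registry of numbering maps.
#' @param domains Optional named list of `domain_structure`s for wild-type
#'   cross-checking against the structure sequence.
#' @return List: `domain` (label or `"inter-domain"`), `local_index`.
#' @export
map_variant <- function(uniprot_position, wt, mut, registry, domains = NULL) {
  local <- uniprot_position - registry$offset
  hit <- which(local >= 1 & local <= registry$length)
  if (!length(hit)) {
    return(list(domain = "inter-domain", local_index = NA_integer_))
  }
  hit <- hit[1]
  li <- local[hit]
  lab <- registry$domain[hit]
  if (!is.null(domains) && lab %in% names(domains)) {
    rt <- residue_table(domains[[lab]])
    aa <- rt$aa[match(li, rt$local_index)]
    if (!is.na(aa) && aa != wt) {
      stop("wild-type mismatch at ", lab, " position ", li,
           ": structure has ", aa, ", variant says ", wt)
    }
  }
  list(domain = lab, local_index = li)
}

#' Structural context of a residue site
#'
#' Classifies a site from its topology state and relative accessibility:
#' `Hydrophobic core` below `core_rel_asa` relative accessibility, else
#' `Loop` for loop/3-10 states, else `β-strand, exposed` for accessible
#' strand residues, otherwise `Surface`. Glycine has no side chain, so the
#' all-atom residue accessibility used here covers that case naturally.
#'
#' @param domain A `domain_structure`.
#' @param local_index Residue local index.
#' @param topology A `sheet_assignment` from [assign_topology()]; computed
#'   if missing.
#' @param accessibility Data frame from [residue_accessibility()]; computed
#'   if missing.
#' @param core_rel_asa Core cutoff in %, default from [impact_rules()].
#' @return One of `"Hydrophobic core"`, `"Loop"`, `"\u03b2-strand, exposed"`,
#'   `"Surface"`.
#' @export
classify_site <- function(domain, local_index, topology = NULL,
                          accessibility = NULL,
                          core_rel_asa = impact_rules()$core_rel_asa) {
  if (is.null(topology)) topology <- assign_topology(domain)
  if (is.null(accessibility)) accessibility <- residue_accessibility(domain)
  rel <- accessibility$rel_asa[match(local_index, accessibility$local_index)]
  state <- topology$residues$state[match(local_index,
                                         topology$residues$local_index)]
  if (is.na(rel) || is.na(state)) stop("residue ", local_index, " not found")
  if (rel < core_rel_asa) return("Hydrophobic core")
  if (state %in% c("loop", "3-10")) return("Loop")
  if (state == "strand") return("\u03b2-strand, exposed")
  "Surface"
}

same_group <- function(wt, mut, groups) {
  any(vapply(groups, function(g) wt %in% g && mut %in% g, logical(1)))
}

#' Predicted structural impact of a missense variant
#'
#' Transparent rule set approximating expert structural judgement:
#' \itemize{
#' \item core site, stability change provided and at or below the
#'   destabilization cutoff, and a non-conservative substitution →
#'   `"Fold destabilization"`;
#' \item core site with no stability input: mutation to proline/glycine or
#'   from tryptophan/cysteine → `"Fold destabilization"`;
#' \item loop site with glycine wild type or proline mutant →
#'   `"Altered loop conformation"`;
#' \item core site with stability input recorded as `NA` (not assessed) →
#'   `"unassessed"`;
#' \item otherwise `"none"`.
#' }
#'
#' @param structural_context Output of [classify_site()] (or the equivalent
#'   annotation supplied with the variant).
#' @param wt,mut Single-letter residues.
#' @param stability Optional stability change (kcal/mol, negative =
#'   destabilizing); use `NA` for "not assessed", `NULL` when the input has
#'   no stability column at all.
#' @param rules Rule thresholds, see [impact_rules()].
#' @return Impact label.
#' @export
annotate_impact <- function(structural_context, wt, mut, stability = NULL,
                            rules = impact_rules()) {
  is_core <- structural_context == "Hydrophobic core"
  is_loop <- structural_context == "Loop"
  if (is_loop && (wt == "G" || mut == "P")) {
    return("Altered loop conformation")
  }
  if (is_core) {
    if (is.null(stability)) {
      if (mut %in% c("P", "G") || wt %in% c("W", "C")) {
        return("Fold destabilization")
      }
    } else if (is.na(stability)) {
      return("unassessed")
    } else if (stability <= rules$destab_cutoff &&
               !same_group(wt, mut, rules$conservative_groups)) {
      return("Fold destabilization")
    }
  }
  "none"
}

#' Read a variant table
#'
#' Expects a TSV with columns `domain` (optional), `wt`, `mut`,
#' `uniprot_position` and optionally `local_index`, `stability`,
#' `frequency`, `rsid`, `conservation_flag`, `structure`, `impact` (the
#' last two being printed annotations usable as inputs when no coordinates
#' are available).
#'
#' @param path TSV path.
#' @return Data frame.
#' @export
read_variants <- function(path) {
  v <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                  na.strings = c("NA", ""))
  need <- c("wt", "mut", "uniprot_position")
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("variant table is missing columns: ",
                         paste(miss, collapse = ", "))
  v
}

#' Annotate a variant table with structural context and predicted impact
#'
#' Maps every variant into its domain via the numbering registry, classifies
#' the structural context from coordinates when the domain structure is
#' available (falling back to a supplied `structure` annotation column
#' otherwise), and applies the impact rule set.
#'
#' @param variants Data frame from [read_variants()].
#' @param registry Numbering registry (`domain`, `offset`, `length`).
#' @param domains Optional named list of `domain_structure` objects.
#' @param rules Impact rule thresholds.
#' @return The variant table with `domain`, `local_index`,
#'   `structural_context` and `predicted_impact` columns filled in.
#' @export
annotate_variants <- function(variants, registry, domains = NULL,
                              rules = impact_rules()) {
  n <- nrow(variants)
  variants$domain <- variants$domain %||% NA_character_
  variants$local_index <- NA_integer_
  variants$structural_context <- NA_character_
  variants$predicted_impact <- NA_character_
  cache <- list()
  for (i in seq_len(n)) {
    mv <- map_variant(variants$uniprot_position[i], variants$wt[i],
                      variants$mut[i], registry, domains)
    variants$domain[i] <- mv$domain
    variants$local_index[i] <- mv$local_index
    if (mv$domain == "inter-domain") next
    ctx <- NA_character_
    if (!is.null(domains) && mv$domain %in% names(domains)) {
      if (is.null(cache[[mv$domain]])) {
        d <- domains[[mv$domain]]
        cache[[mv$domain]] <- list(topo = assign_topology(d),
                                   acc = residue_accessibility(d),
                                   domain = d)
      }
      cc <- cache[[mv$domain]]
      ctx <- classify_site(cc$domain, mv$local_index, cc$topo, cc$acc,
                           core_rel_asa = rules$core_rel_asa)
    } else if ("structure" %in% names(variants) && !is.na(variants$structure[i])) {
      ctx <- variants$structure[i]
    }
    variants$structural_context[i] <- ctx
    if (!is.na(ctx)) {
      stab <- if ("stability" %in% names(variants)) {
        variants$stability[i]
      } else {
        NULL
      }
      variants$predicted_impact[i] <- annotate_impact(
        ctx, variants$wt[i], variants$mut[i], stab, rules)
    }
  }
  variants
}

`%||%` <- function(a, b) if (is.null(a)) b else a
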