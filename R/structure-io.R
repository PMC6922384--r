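#' @importFrom stats setNames
#' @importFrom utils read.delim write.table head tail
NULL

ATOM_COLS <- c("type", "eleno", "elety", "alt", "resid", "chain", "resno",
               "insert", "x", "y", "z", "o", "b", "elesy")

#' Read a protein coordinate file
#'
#' Parses a PDB-format coordinate file into a multi-chain structure model.
#' ATOM and HETATM records are kept apart so that waters and ligands never
#' enter residue-level analyses but remain available for metal-site and
#' disulfide detection. For multi-model files (NMR ensembles) a single model
#' is loaded.
#'
#' @param path Path to a PDB file.
#' @param format Input format; only `"pdb"` is supported.
#' @param model Model number to load from multi-model files (default 1).
#' @return A `structure_model` object: a list with `atoms` (protein ATOM
#'   records as a data frame), `hetero` (HETATM records), `path` and
#'   `model_number`.
#' @export
read_structure <- function(path, format = "pdb", model = 1L) {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  if (!any(grepl("^ATOM", rec))) {
    bad <- if (length(lines)) lines[1] else "<empty file>"
    stop("not a parseable PDB file (no ATOM records); first line: ", bad)
  }
  n_models <- sum(grepl("^MODEL", rec))
  multi <- n_models > 1
  pdb <- bio3d::read.pdb(path, multi = multi, rm.alt = FALSE, verbose = FALSE)
  atoms <- pdb$atom
  if (multi) {
    if (model < 1 || model > nrow(pdb$xyz)) {
      stop("model ", model, " not present (file has ", n_models, " models)")
    }
    xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
    atoms$x <- xyz[, 1]
    atoms$y <- xyz[, 2]
    atoms$z <- xyz[, 3]
  }
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$o[is.na(atoms$o)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  atoms$elesy[is.na(atoms$elesy) | atoms$elesy == ""] <-
    guess_element(atoms$elety[is.na(atoms$elesy) | atoms$elesy == ""])
  is_het <- atoms$type == "HETATM"
  out <- list(
    atoms = atoms[!is_het, , drop = FALSE],
    hetero = atoms[is_het, , drop = FALSE],
    path = path,
    model_number = as.integer(model)
  )
  class(out) <- "structure_model"
  out
}

guess_element <- function(elety) {
  e <- sub("^[0-9]*", "", trimws(elety))
  ifelse(nchar(e) > 0, substr(e, 1, 1), "C")
}

#' @export
print.structure_model <- function(x, ...) {
  ch <- model_chains(x)
  cat("structure_model:", length(ch), "chain(s) [", paste(ch, collapse = ", "),
      "],", nrow(x$atoms), "protein atoms,", nrow(x$hetero), "hetero atoms\n")
  invisible(x)
}

#' Chains present in a structure model
#' @param model A `structure_model`.
#' @return Character vector of chain identifiers, in file order.
#' @export
model_chains <- function(model) {
  unique(model$atoms$chain)
}

#' Assemble a structure model from domain structures
#'
#' Builds a multi-chain `structure_model` from one or more
#' `domain_structure` objects, e.g. to analyse intermolecular disulfides in
#' a synthetic dimer.
#'
#' @param domains List of `domain_structure` objects; each becomes one chain.
#' @param chain_ids Chain identifiers, defaults to A, B, C, ...
#' @return A `structure_model`.
#' @export
combine_model <- function(domains, chain_ids = LETTERS[seq_along(domains)]) {
  stopifnot(length(domains) == length(chain_ids))
  atoms <- do.call(rbind, lapply(seq_along(domains), function(i) {
    a <- domains[[i]]$atoms[, ATOM_COLS]
    a$chain <- chain_ids[i]
    a
  }))
  atoms$eleno <- seq_len(nrow(atoms))
  het <- do.call(rbind, lapply(domains, function(d) {
    if (is.null(d$hetero) || nrow(d$hetero) == 0) NULL else d$hetero[, ATOM_COLS]
  }))
  if (is.null(het)) {
    het <- atoms[0, , drop = FALSE]
  }
  out <- list(atoms = atoms, hetero = het, path = NA_character_,
              model_number = 1L)
  class(out) <- "structure_model"
  out
}

#' Extract one analysis chain as an Ig-domain structure
#'
#' Selects a single chain from a model, collapses alternate conformers to the
#' highest-occupancy one (ties resolved toward altloc "A"), excludes
#' hetero-atoms and waters from the residue list (they are kept in a side
#' table for metal-site detection), and assigns a 1-based local residue index
#' along the chain. Chain preference `"auto"` selects chain A when present,
#' otherwise the first chain in the file, following the convention used for
#' multi-copy crystal forms.
#'
#' @param model A `structure_model` from [read_structure()] or
#'   [combine_model()].
#' @param chain Chain id, or `"auto"`.
#' @param domain_label Label such as `"M1"` ... `"M10"` or a synthetic tag.
#' @param pdb_id 4-character PDB code or `"synthetic"`.
#' @param tag_local Local indices of residues left over from a cleaved
#'   expression tag; they stay in the structure but are flagged and excluded
#'   from alignment and fingerprint computations.
#' @return A `domain_structure` object.
#' @export
extract_domain <- function(model, chain = "auto", domain_label = "domain",
                           pdb_id = "unknown", tag_local = integer()) {
  chains <- model_chains(model)
  if (identical(chain, "auto")) {
    chain <- if ("A" %in% chains) "A" else chains[1]
  }
  if (!chain %in% chains) {
    stop("chain '", chain, "' not found; available chains: ",
         paste(chains, collapse = ", "))
  }
  atoms <- model$atoms[model$atoms$chain == chain, , drop = FALSE]
  if (any(atoms$insert != "")) {
    stop("insertion codes are not supported within a domain (residue ",
         atoms$resno[atoms$insert != ""][1], ")")
  }
  atoms <- collapse_altloc(atoms)
  ## drop hydrogens: all heavy-atom analyses reconstruct H geometrically
  atoms <- atoms[atoms$elesy != "H", , drop = FALSE]
  resno <- atoms$resno
  ridx <- cumsum(!duplicated(resno))  # file order; resno assumed monotone per chain
  ures <- resno[!duplicated(resno)]
  atoms$local_index <- match(resno, ures)
  atoms$tag <- atoms$local_index %in% tag_local
  out <- list(
    domain_label = domain_label,
    pdb_id = pdb_id,
    source_chain = chain,
    model_number = model$model_number,
    atoms = atoms,
    hetero = model$hetero,
    numbering = list(offset = NA_integer_, uniprot_id = NA_character_)
  )
  class(out) <- "domain_structure"
  out
}

collapse_altloc <- function(atoms) {
  if (all(atoms$alt == "")) {
    return(atoms)
  }
  key <- paste(atoms$resno, atoms$elety)
  ord <- order(key, -atoms$o, atoms$alt)
  a <- atoms[ord, , drop = FALSE]
  a <- a[!duplicated(paste(a$resno, a$elety)), , drop = FALSE]
  a[order(a$eleno), , drop = FALSE]
}

#' @export
print.domain_structure <- function(x, ...) {
  cat("domain_structure", x$domain_label, "(", x$pdb_id, ") chain",
      x$source_chain, ":", n_residues(x), "residues,", nrow(x$atoms),
      "atoms\n")
  invisible(x)
}

#' Number of residues in a domain
#' @param domain A `domain_structure`.
#' @return Integer residue count.
#' @export
n_residues <- function(domain) {
  length(unique(domain$atoms$local_index))
}

#' Residue-level summary of a domain
#'
#' @param domain A `domain_structure`.
#' @return Data frame with one row per residue: `local_index`, author
#'   `resno`, three-letter `resid`, one-letter `aa`, `tag` flag and a
#'   `backbone_complete` flag (TRUE iff N, CA, C and O are all present).
#' @export
residue_table <- function(domain) {
  a <- domain$atoms
  idx <- sort(unique(a$local_index))
  bb <- vapply(idx, function(i) {
    all(c("N", "CA", "C", "O") %in% a$elety[a$local_index == i])
  }, logical(1))
  first <- match(idx, a$local_index)
  data.frame(
    local_index = idx,
    resno = a$resno[first],
    resid = a$resid[first],
    aa = bio3d::aa321(a$resid[first]),
    tag = a$tag[first],
    backbone_complete = bb,
    stringsAsFactors = FALSE
  )
}

#' One-letter amino-acid sequence of a domain
#' @param domain A `domain_structure`.
#' @param exclude_tag Drop residues flagged as cleaved-tag leftovers.
#' @return Single character string.
#' @export
domain_sequence <- function(domain, exclude_tag = TRUE) {
  rt <- residue_table(domain)
  if (exclude_tag) {
    rt <- rt[!rt$tag, , drop = FALSE]
  }
  paste(rt$aa, collapse = "")
}

#' Cα coordinate matrix of a domain
#' @param domain A `domain_structure`.
#' @param exclude_tag Drop cleaved-tag residues.
#' @return n x 3 matrix of Cα coordinates (Å), rownames = local indices.
#' @export
ca_coords <- function(domain, exclude_tag = TRUE) {
  a <- domain$atoms
  a <- a[a$elety == "CA", , drop = FALSE]
  if (exclude_tag) {
    a <- a[!a$tag, , drop = FALSE]
  }
  m <- as.matrix(a[, c("x", "y", "z")])
  rownames(m) <- a$local_index
  m
}

#' Dual residue numbering for a domain
#'
#' A numbering map ties the 1-based domain-local index to the position in the
#' full-length titin sequence: `global = local + offset`.
#'
#' @param offset Integer offset (UniProt position minus local index).
#' @param uniprot_id Accession of the full-length sequence (e.g. the human
#'   titin entry the renumbering refers to).
#' @return A `numbering_map` object.
#' @export
numbering_map <- function(offset, uniprot_id = NA_character_) {
  stopifnot(is.numeric(offset), length(offset) == 1)
  structure(list(offset = as.integer(offset), uniprot_id = uniprot_id),
            class = "numbering_map")
}

#' Attach a numbering map to a domain
#' @param domain A `domain_structure`.
#' @param map A `numbering_map`.
#' @return The domain with dual numbering attached.
#' @export
apply_numbering <- function(domain, map) {
  stopifnot(inherits(map, "numbering_map"))
  domain$numbering <- list(offset = map$offset, uniprot_id = map$uniprot_id)
  domain
}

#' Convert between local and global (full-titin) numbering
#' @param domain A `domain_structure` with a numbering map.
#' @param local Local indices.
#' @return Global UniProt positions.
#' @export
local_to_global <- function(domain, local) {
  off <- domain$numbering$offset
  if (is.na(off)) stop("domain has no numbering map")
  local + off
}

#' @rdname local_to_global
#' @param global Global UniProt positions.
#' @export
global_to_local <- function(domain, global) {
  off <- domain$numbering$offset
  if (is.na(off)) stop("domain has no numbering map")
  global - off
}

#' Write a domain or model to a PDB file
#'
#' Emits fixed-width PDB v3.3 ATOM/HETATM records with coordinates to three
#' decimals, so that a read/write round trip reproduces coordinates exactly
#' at that precision. For a renumbered copy, set `numbering = "local"`
#' (author numbers become the 1-based domain index) or `"global"` (full-titin
#' UniProt positions).
#'
#' @param x A `domain_structure` or `structure_model`.
#' @param path Output path.
#' @param numbering One of `"author"`, `"local"`, `"global"` (domains only).
#' @param hetero Include the hetero-atom side table.
#' @return Invisibly, the path.
#' @export
write_pdb <- function(x, path, numbering = c("author", "local", "global"),
                      hetero = FALSE) {
  numbering <- match.arg(numbering)
  if (inherits(x, "domain_structure")) {
    atoms <- x$atoms
    if (nrow(atoms) == 0) stop("cannot write an empty domain")
    if (numbering == "local") {
      atoms$resno <- atoms$local_index
    } else if (numbering == "global") {
      atoms$resno <- local_to_global(x, atoms$local_index)
    }
  } else if (inherits(x, "structure_model")) {
    atoms <- x$atoms
    if (nrow(atoms) == 0) stop("cannot write an empty model")
  } else {
    stop("x must be a domain_structure or structure_model")
  }
  if (any(atoms$resno > 9999 | atoms$resno < -999)) {
    stop("residue numbers outside the PDB fixed-width range (-999..9999)")
  }
  recs <- format_pdb_records(atoms)
  if (hetero) {
    het <- if (inherits(x, "domain_structure")) x$hetero else x$hetero
    if (!is.null(het) && nrow(het) > 0) {
      recs <- c(recs, format_pdb_records(het))
    }
  }
  writeLines(c(recs, "END"), path)
  invisible(path)
}

format_pdb_records <- function(atoms) {
  name <- ifelse(nchar(atoms$elety) >= 4, substr(atoms$elety, 1, 4),
                 sprintf(" %-3s", atoms$elety))
  sprintf("%-6s%5d %4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$type, atoms$eleno %% 100000L, name,
          substr(paste0(atoms$alt, " "), 1, 1),
          atoms$resid, atoms$chain, atoms$resno,
          substr(paste0(atoms$insert, " "), 1, 1),
          atoms$x, atoms$y, atoms$z, atoms$o, atoms$b, atoms$elesy)
}

#' Read a domain registry configuration
#'
#' The registry is a tab-separated table mapping domain labels to coordinate
#' files and numbering offsets, with columns `domain`, `file`, `chain`,
#' `offset`, `uniprot_id` and optionally `pdb_id`, `model`, `tag_local`
#' (comma-separated local indices of cleaved-tag residues).
#'
#' @param path Path to the TSV registry.
#' @param base_dir Directory that relative `file` entries are resolved
#'   against (defaults to the registry's own directory).
#' @return Data frame of registry rows.
#' @export
read_registry <- function(path, base_dir = dirname(path)) {
  reg <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("domain", "file", "chain", "offset", "uniprot_id")
  miss <- setdiff(need, names(reg))
  if (length(miss)) stop("registry is missing columns: ", paste(miss, collapse = ", "))
  rel <- !is.na(reg$file) & reg$file != "" & !grepl("^/", reg$file)
  reg$file[rel] <- file.path(base_dir, reg$file[rel])
  reg
}

#' Load all domains listed in a registry
#'
#' @param registry Data frame from [read_registry()].
#' @return Named list of `domain_structure` objects (names = domain labels).
#' @export
load_registry_domains <- function(registry) {
  out <- list()
  for (i in seq_len(nrow(registry))) {
    r <- registry[i, ]
    model_no <- if ("model" %in% names(registry) && !is.na(r$model)) r$model else 1L
    m <- read_structure(r$file, model = model_no)
    tag <- integer()
    if ("tag_local" %in% names(registry) && !is.na(r$tag_local) && r$tag_local != "") {
      tag <- as.integer(strsplit(as.character(r$tag_local), ",")[[1]])
    }
    pdb_id <- if ("pdb_id" %in% names(registry)) r$pdb_id else "unknown"
    d <- extract_domain(m, chain = r$chain, domain_label = r$domain,
                        pdb_id = pdb_id, tag_local = tag)
    d <- apply_numbering(d, numbering_map(r$offset, r$uniprot_id))
    out[[r$domain]] <- d
  }
  out
}
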