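# Drug featurization: offline name->SMILES resolution and the fixed
# 14-descriptor vector computed with ChemmineR/OpenBabel.

#' Offline drug structure cache
#'
#' A curated table mapping drug names to canonical SMILES, shipped with the
#' package and vendored at build time from public compound records
#' (validated against each compound's molecular formula). Biologic entries
#' (proteins/peptides such as insulin or VEGF) are present with an empty
#' structure and `kind = "biologic"`: they have no small-molecule structure
#' and their descriptors are left missing for downstream mean imputation.
#'
#' @return data.frame with columns `drug_name`, `smiles`, `kind`,
#'   `formula`.
#' @export
drug_structure_cache <- function() {
  read.csv(system.file("extdata", "drug_structures.csv",
                       package = "plgarelease", mustWork = TRUE),
           stringsAsFactors = FALSE)
}

#' Resolve a drug name to a structure string
#'
#' Looks the name up (case-insensitively) in the offline cache first. An
#' online compound-database lookup is attempted only when `allow_online =
#' TRUE` and the name is absent from the cache; the package never goes
#' online by default and its tests never do.
#'
#' @param drug_name drug name, non-empty.
#' @param cache structure table, defaults to [drug_structure_cache()].
#' @param allow_online permit a PubChem REST lookup for unknown names.
#' @return The canonical SMILES string, or `NA_character_` for a known
#'   biologic without a small-molecule structure (callers must then supply
#'   descriptors or rely on imputation).
#' @export
#' @examples
#' resolve_structure("Ibuprofen")
resolve_structure <- function(drug_name, cache = drug_structure_cache(),
                              allow_online = FALSE) {
  if (!is.character(drug_name) || length(drug_name) != 1L ||
      is.na(drug_name) || !nzchar(trimws(drug_name))) {
    stop("drug_name must be a non-empty string", call. = FALSE)
  }
  i <- match(tolower(trimws(drug_name)), tolower(cache$drug_name))
  if (!is.na(i)) {
    if (identical(cache$kind[i], "biologic") || !nzchar(cache$smiles[i])) {
      return(NA_character_)
    }
    return(cache$smiles[i])
  }
  if (allow_online) {
    smi <- try(pubchem_smiles(drug_name), silent = TRUE)
    if (!inherits(smi, "try-error") && length(smi) == 1L && nzchar(smi)) {
      return(smi)
    }
  }
  stop("cannot resolve drug name: ", drug_name,
       if (!allow_online) " (online lookup disabled)", call. = FALSE)
}

pubchem_smiles <- function(name) {
  url <- paste0("https://pubchem.ncbi.nlm.nih.gov/rest/pug/compound/name/",
                utils::URLencode(name, reserved = TRUE),
                "/property/CanonicalSMILES/TXT")
  trimws(readLines(url, warn = FALSE)[1])
}

#' Compute the 14-dimensional drug descriptor vector
#'
#' Parses a SMILES string (via OpenBabel) and computes, in this fixed
#' order: molecular weight (g/mol), logP, hydrogen-bond donor and acceptor
#' counts, heavy atom count, rotatable bond count, topological polar
#' surface area (A^2), ring count (smallest set of smallest rings),
#' aromatic ring count, molar refractivity, and the four Lipinski
#' rule-of-five pass flags (MW <= 500, logP <= 5, HBD <= 5, HBA <= 10,
#' each 1 = pass). The flags are always derived from the computed
#' continuous values, never supplied independently.
#'
#' Rotatable bonds are counted on the molecular graph as acyclic single
#' bonds between two non-terminal heavy atoms, excluding bonds adjacent to
#' a triple bond (the common strict definition).
#'
#' @param smiles a SMILES string.
#' @return named numeric vector of length 14 (names =
#'   [descriptor_features()]).
#' @export
#' @examples
#' \donttest{
#' compute_descriptors("CCO")  # ethanol
#' }
compute_descriptors <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) ||
      !nzchar(smiles)) {
    stop("smiles must be a non-empty string", call. = FALSE)
  }
  sdf <- try(suppressWarnings(ChemmineR::smiles2sdf(smiles)), silent = TRUE)
  if (inherits(sdf, "try-error") || length(sdf) == 0L) {
    stop("cannot parse structure: ", smiles, call. = FALSE)
  }
  props <- ChemmineR::propOB(sdf)
  ringinfo <- ChemmineR::rings(sdf, inner = TRUE, type = "count",
                               arom = TRUE)
  # one molecule yields a plain named vector, several a matrix
  if (is.null(dim(ringinfo))) ringinfo <- rbind(ringinfo)
  graph <- mol_graph(sdf[[1]])

  mw <- as.numeric(props$MW)
  logp <- as.numeric(props$logP)
  hbd <- as.numeric(props$HBD)
  hba <- as.numeric(props$HBA1)
  out <- c(
    molecular_weight = mw,
    logp = logp,
    hbd_count = hbd,
    hba_count = hba,
    heavy_atom_count = graph$n_heavy,
    rotatable_bond_count = count_rotatable(graph),
    tpsa = as.numeric(props$TPSA),
    ring_count = as.numeric(ringinfo[1, "RINGS"]),
    aromatic_ring_count = as.numeric(ringinfo[1, "AROMATIC"]),
    molar_refractivity = as.numeric(props$MR),
    lipinski_mw_ok = as.numeric(mw <= 500),
    lipinski_logp_ok = as.numeric(logp <= 5),
    lipinski_hbd_ok = as.numeric(hbd <= 5),
    lipinski_hba_ok = as.numeric(hba <= 10)
  )
  stopifnot(identical(names(out), descriptor_features()))
  out
}

# Heavy-atom connectivity extracted from an SDF block.
mol_graph <- function(sdfmol) {
  ab <- ChemmineR::atomblock(sdfmol)
  elements <- gsub("_.*$", "", rownames(ab))
  heavy <- elements != "H"
  bb <- ChemmineR::bondblock(sdfmol)
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L) {
    matrix(numeric(0), 0, 3)
  } else {
    cbind(as.numeric(bb[, 1]), as.numeric(bb[, 2]), as.numeric(bb[, 3]))
  }
  keep <- heavy[bonds[, 1]] & heavy[bonds[, 2]]
  bonds <- bonds[keep, , drop = FALSE]
  list(n_heavy = sum(heavy), bonds = bonds)
}

count_rotatable <- function(graph) {
  b <- graph$bonds
  if (nrow(b) == 0L) return(0)
  deg <- tabulate(c(b[, 1], b[, 2]), nbins = max(c(b[, 1:2], 1)))
  in_triple <- unique(c(b[b[, 3] == 3, 1], b[b[, 3] == 3, 2]))
  n_rot <- 0L
  for (i in seq_len(nrow(b))) {
    if (b[i, 3] != 1) next                       # single bonds only
    a1 <- b[i, 1]; a2 <- b[i, 2]
    if (deg[a1] < 2 || deg[a2] < 2) next          # terminal atoms
    if (a1 %in% in_triple || a2 %in% in_triple) next
    if (!is_bridge(b, i)) next                    # ring bonds never rotate
    n_rot <- n_rot + 1L
  }
  n_rot
}

# A bond is acyclic iff it is a bridge: removing it disconnects its ends.
is_bridge <- function(bonds, i) {
  from <- bonds[i, 1]; to <- bonds[i, 2]
  rest <- bonds[-i, 1:2, drop = FALSE]
  seen <- from
  frontier <- from
  while (length(frontier)) {
    nb <- c(rest[rest[, 1] %in% frontier, 2], rest[rest[, 2] %in% frontier, 1])
    nb <- setdiff(unique(nb), seen)
    if (to %in% nb) return(FALSE)
    seen <- c(seen, nb)
    frontier <- nb
  }
  TRUE
}

#' Attach computed descriptors to a dataset
#'
#' Resolves each sample's structure (from its `smiles` column, falling back
#' to name resolution through the offline cache) and fills the fourteen
#' descriptor columns. Samples without a structure (biologics) keep missing
#' descriptors; run [impute_missing()] afterwards.
#'
#' @param dataset a `release_dataset`.
#' @param cache structure table for name resolution.
#' @return The dataset with descriptor columns populated where possible.
#' @export
add_descriptors <- function(dataset, cache = drug_structure_cache()) {
  stopifnot(inherits(dataset, "release_dataset"))
  s <- dataset$samples
  memo <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(s))) {
    smi <- s$smiles[i]
    if (is.na(smi) || !nzchar(smi)) {
      smi <- tryCatch(resolve_structure(s$drug_name[i], cache = cache),
                      error = function(e) NA_character_)
      s$smiles[i] <- smi
    }
    if (is.na(smi) || !nzchar(smi)) next
    key <- smi
    d <- if (!is.null(memo[[key]])) memo[[key]] else {
      memo[[key]] <- compute_descriptors(smi)
      memo[[key]]
    }
    s[i, descriptor_features()] <- as.list(d)
  }
  dataset$samples <- s
  dataset
}
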