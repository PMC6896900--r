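HISTONE_ROLES <- c("H3", "H4", "H2A", "H2B", "H3'", "H4'", "H2A'", "H2B'")
DNA_ROLES <- c("DNA-I", "DNA-J")

#' Default chain-id to role map (1KX5 convention)
#'
#' Chains A-H are the eight histones (H3, H4, H2A, H2B and their primed
#' copies), chains I and J the two DNA strands.
#'
#' @return Named character vector mapping chain id to role.
#' @export
default_chain_map <- function() {
  c(A = "H3", B = "H4", C = "H2A", D = "H2B",
    E = "H3'", F = "H4'", G = "H2A'", H = "H2B'",
    I = "DNA-I", J = "DNA-J")
}

#' Default histone core/tail region table
#'
#' Residue ranges delimiting the folded histone core and the disordered
#' tails, in the numbering of the source structure. H2A carries both an
#' N-terminal and a C-terminal tail; the other histones only an N-terminal
#' one. Primed histones share the ranges of their unprimed partners.
#'
#' @return A data.frame with columns `role`, `region` ("core", "tail_n",
#'   "tail_c"), `from`, `to`.
#' @export
default_region_table <- function() {
  base <- data.frame(
    role = c("H3", "H3", "H4", "H4",
             "H2A", "H2A", "H2A", "H2B", "H2B"),
    region = c("core", "tail_n", "core", "tail_n",
               "core", "tail_n", "tail_c", "core", "tail_n"),
    from = c(45L, 1L, 25L, 1L, 18L, 1L, 99L, 35L, 1L),
    to   = c(135L, 44L, 102L, 24L, 98L, 17L, 128L, 122L, 34L),
    stringsAsFactors = FALSE
  )
  primed <- base
  primed$role <- paste0(primed$role, "'")
  rt <- rbind(base, primed)
  validate_region_table(rt)
  rt
}

validate_region_table <- function(rt) {
  stopifnot(is.data.frame(rt),
            all(c("role", "region", "from", "to") %in% names(rt)))
  if (any(rt$from > rt$to)) stop("region table: 'from' exceeds 'to'")
  for (role in unique(rt$role)) {
    sub <- rt[rt$role == role, ]
    core <- sub[sub$region == "core", ]
    tails <- sub[sub$region != "core", ]
    if (nrow(core) != 1L) stop("region table: role ", role, " needs exactly one core range")
    for (k in seq_len(nrow(tails))) {
      if (tails$from[k] <= core$to && tails$to[k] >= core$from)
        stop("region table: core and tail overlap for role ", role)
    }
  }
  invisible(rt)
}

#' Construct a ComplexTopology
#'
#' @param atoms data.frame with columns `atom_id`, `atom_name`, `element`,
#'   `chain_id`, `residue_index`, `residue_name`. Row order is atom order.
#' @param chain_map named character vector, chain id -> role.
#' @return An object of class `ComplexTopology`.
#' @export
complex_topology <- function(atoms, chain_map = default_chain_map()) {
  need <- c("atom_id", "atom_name", "element", "chain_id",
            "residue_index", "residue_name")
  missing <- setdiff(need, names(atoms))
  if (length(missing)) stop("atoms lacks columns: ", paste(missing, collapse = ", "))
  chains <- unique(atoms$chain_id)
  unknown <- setdiff(chains, names(chain_map))
  if (length(unknown))
    stop("chains without a role in chain_map: ", paste(unknown, collapse = ", "))
  structure(
    list(atoms = atoms,
         chain_roles = chain_map[chains],
         chain_ids = chains),
    class = "ComplexTopology")
}

#' @export
print.ComplexTopology <- function(x, ...) {
  cat("ComplexTopology:", nrow(x$atoms), "atoms,",
      length(x$chain_ids), "chains\n")
  for (ch in x$chain_ids) {
    n <- sum(x$atoms$chain_id == ch)
    cat(sprintf("  chain %s (%s): %d atoms\n", ch, x$chain_roles[[ch]], n))
  }
  invisible(x)
}

n_atoms <- function(topology) nrow(topology$atoms)

chain_role <- function(topology, chain_id) topology$chain_roles[[chain_id]]

histone_chains <- function(topology) {
  topology$chain_ids[topology$chain_roles %in% HISTONE_ROLES]
}

dna_chains <- function(topology) {
  topology$chain_ids[topology$chain_roles %in% DNA_ROLES]
}

is_canonical <- function(topology) {
  length(histone_chains(topology)) == 8L && length(dna_chains(topology)) == 2L
}

VARIANTS <- c("canonical", "dH3/H4", "dH2A/H2B", "dH3'/H4'", "dH2A'/H2B'")

#' Chains deleted by a model variant
#'
#' Variant names follow the dimer that is removed: `"dH3/H4"` deletes chains
#' A and B, `"dH2A/H2B"` chains C and D, `"dH3'/H4'"` chains E and F,
#' `"dH2A'/H2B'"` chains G and H (1KX5 convention). `"canonical"` deletes
#' nothing.
#'
#' @param variant one of `model_variants()`.
#' @return Character vector of roles to delete (length 0 or 2).
#' @export
variant_deleted_roles <- function(variant) {
  variant <- match.arg(variant, VARIANTS)
  switch(variant,
         "canonical"  = character(0),
         "dH3/H4"     = c("H3", "H4"),
         "dH2A/H2B"   = c("H2A", "H2B"),
         "dH3'/H4'"   = c("H3'", "H4'"),
         "dH2A'/H2B'" = c("H2A'", "H2B'"))
}

#' @rdname variant_deleted_roles
#' @export
model_variants <- function() VARIANTS

#' Build a single-dimer-deletion variant of a canonical topology
#'
#' Removes the two chains of the named dimer; atom ordering of surviving
#' chains, and the DNA, are untouched. Residues are never renumbered.
#'
#' @param topology canonical `ComplexTopology` (all 8 histone + 2 DNA chains).
#' @param variant one of `model_variants()`.
#' @param coords optional n_atoms x 3 coordinate matrix filtered in step.
#' @return The reduced topology, or `list(topology, coords)` when `coords`
#'   is given.
#' @export
build_variant <- function(topology, variant, coords = NULL) {
  variant <- match.arg(variant, VARIANTS)
  roles <- variant_deleted_roles(variant)
  if (length(roles) == 0L) {
    if (is.null(coords)) return(topology)
    return(list(topology = topology, coords = coords))
  }
  if (!is_canonical(topology))
    stop("build_variant: topology is already reduced; deletions apply to the canonical form only")
  del_chains <- topology$chain_ids[topology$chain_roles %in% roles]
  if (length(del_chains) != 2L)
    stop("build_variant: chains for roles ", paste(roles, collapse = "/"),
         " not present in topology")
  keep <- !(topology$atoms$chain_id %in% del_chains)
  atoms <- topology$atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  out <- complex_topology(atoms, topology$chain_roles[setdiff(topology$chain_ids, del_chains)])
  if (is.null(coords)) return(out)
  list(topology = out, coords = coords[keep, , drop = FALSE])
}

SELECTION_LABELS <- c("align_all_no_tails", "align_histone_core_only",
                      "dna_c1p", "histone_ca", "custom")

hydrogen_flag <- function(atoms) {
  el <- toupper(trimws(atoms$element))
  el == "H" | el == "D"
}

#' Classify histone residues into core/tail by the region table
#'
#' @keywords internal
classify_residue <- function(role, residue_index, region_table) {
  sub <- region_table[region_table$role == role, , drop = FALSE]
  hit <- sub$from <= residue_index & residue_index <= sub$to
  if (!any(hit)) return(NA_character_)
  sub$region[which(hit)[1]]
}

#' Build an atom SelectionMask realizing an alignment convention
#'
#' Labels:
#' * `align_all_no_tails`: all heavy atoms except histone-tail residues
#'   (alignment convention for the whole complex).
#' * `align_histone_core_only`: heavy atoms of histone core residues only,
#'   DNA excluded (alignment convention for DNA-deformation analyses).
#' * `dna_c1p`: exactly one C1' atom per nucleotide.
#' * `histone_ca`: exactly one CA atom per amino acid.
#'
#' Residues outside the structure are skipped; a histone residue covered by
#' no region of the table is an error. Hydrogens are excluded from every
#' mask.
#'
#' @param topology `ComplexTopology`.
#' @param region_table data.frame as `default_region_table()`.
#' @param label one of the labels above.
#' @param indices explicit 1-based atom indices when `label = "custom"`.
#' @return Object of class `SelectionMask`: list(indices, label).
#' @export
make_selection <- function(topology, region_table = default_region_table(),
                           label = SELECTION_LABELS, indices = NULL) {
  label <- match.arg(label, SELECTION_LABELS)
  atoms <- topology$atoms
  if (label == "custom") {
    if (is.null(indices)) stop("custom selection requires indices")
    if (length(indices) && (min(indices) < 1L || max(indices) > nrow(atoms)))
      stop("custom selection indices out of range")
    return(new_mask(as.integer(indices), label))
  }
  heavy <- !hydrogen_flag(atoms)
  role <- unname(topology$chain_roles[atoms$chain_id])
  is_hist <- role %in% HISTONE_ROLES
  is_dna <- role %in% DNA_ROLES

  if (label == "dna_c1p") {
    idx <- which(is_dna & atoms$atom_name == "C1'")
    check_one_per_residue(atoms, is_dna, idx, "C1'")
    return(new_mask(idx, label))
  }
  if (label == "histone_ca") {
    idx <- which(is_hist & atoms$atom_name == "CA")
    check_one_per_residue(atoms, is_hist, idx, "CA")
    return(new_mask(idx, label))
  }

  region <- rep(NA_character_, nrow(atoms))
  for (ch in topology$chain_ids) {
    r <- topology$chain_roles[[ch]]
    if (!(r %in% HISTONE_ROLES)) next
    sel <- which(atoms$chain_id == ch)
    for (res in unique(atoms$residue_index[sel])) {
      cls <- classify_residue(r, res, region_table)
      if (is.na(cls))
        stop("make_selection: residue ", res, " of chain ", ch,
             " (", r, ") falls in no region of the region table")
      region[sel[atoms$residue_index[sel] == res]] <- cls
    }
  }
  is_tail <- !is.na(region) & region != "core"
  if (label == "align_all_no_tails") {
    idx <- which(heavy & !is_tail & (is_hist | is_dna))
  } else { # align_histone_core_only
    idx <- which(heavy & is_hist & !is.na(region) & region == "core")
  }
  new_mask(idx, label)
}

new_mask <- function(indices, label) {
  structure(list(indices = as.integer(indices), label = label),
            class = "SelectionMask")
}

#' @export
print.SelectionMask <- function(x, ...) {
  cat("SelectionMask <", x$label, ">: ", length(x$indices), " atoms\n", sep = "")
  invisible(x)
}

check_one_per_residue <- function(atoms, in_scope, idx, name) {
  key <- paste(atoms$chain_id, atoms$residue_index)
  have <- unique(key[idx])
  want <- unique(key[in_scope])
  missing <- setdiff(want, have)
  if (length(missing))
    warning("residues lacking a ", name, " atom are omitted from the mask: ",
            paste(utils::head(missing, 5), collapse = "; "),
            if (length(missing) > 5) " ..." else "")
  dup <- any(duplicated(key[idx]))
  if (dup) stop("duplicate ", name, " atom within a residue")
  invisible(NULL)
}

#' Restrict a mask to the atoms surviving a variant deletion
#'
#' Maps atom indices of a canonical-topology mask onto the index space of the
#' reduced topology; deleted atoms drop out.
#'
#' @keywords internal
filter_mask_to_variant <- function(mask, topology, variant) {
  roles <- variant_deleted_roles(variant)
  if (!length(roles)) return(mask)
  del_chains <- topology$chain_ids[topology$chain_roles %in% roles]
  keep <- !(topology$atoms$chain_id %in% del_chains)
  newpos <- cumsum(keep)
  kept <- mask$indices[keep[mask$indices]]
  new_mask(newpos[kept], mask$label)
}
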