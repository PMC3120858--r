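#' Build the 5hmC patch from 5mC and serine parameters
#'
#' Constructs residue parameters for 5-hydroxymethylcytosine from the
#' 5-methylcytosine residue by the hydroxyl-substitution rule: one
#' hydrogen of the C5 methyl group is exchanged for a hydroxyl group whose
#' O and H charges are taken verbatim from the serine hydroxyl; the
#' residual charge is then redistributed uniformly over the remaining
#' CH2 group (the carbon and its two hydrogens) so the residue's net
#' charge is exactly conserved.
#'
#' The methyl group is located structurally: a carbon bonded to exactly
#' three hydrogens within the residue. The serine hydroxyl is the O-H
#' pair (an oxygen bonded to exactly one hydrogen). The deleted hydrogen
#' is the first of the three in topology order — an arbitrary but
#' deterministic choice; at the parameter level the three are equivalent.
#'
#' @param mc_residue residue block (one element of a
#'   [read_charge_topology()] result) containing a methyl group
#' @param serine_residue residue block containing a hydroxyl O-H pair
#' @param hydroxyl_names names for the two added atoms (O then H)
#' @return object of class `flipsite_patch`: list with
#'   `target_residue_name`, `deleted_atoms`, `added_atoms` (data.frame),
#'   `charge_adjustments` (named numeric: new charges), `new_bonds`
#'   (2-column character matrix)
#' @export
build_5hmc_patch <- function(mc_residue, serine_residue,
                             hydroxyl_names = c("OH5", "HO5")) {
  methyl <- find_methyl(mc_residue)
  if (is.null(methyl))
    stop("no methyl group (C bonded to 3 H) found in residue ",
         mc_residue$name)
  hydroxyl <- find_hydroxyl(serine_residue)
  if (is.null(hydroxyl))
    stop("no hydroxyl O-H pair identifiable in residue ",
         serine_residue$name)

  atoms <- mc_residue$atoms
  h_del <- methyl$hydrogens[1]          # first methyl H in topology order
  h_keep <- methyl$hydrogens[-1]
  o_row <- serine_residue$atoms[serine_residue$atoms$name == hydroxyl$o, ]
  h_row <- serine_residue$atoms[serine_residue$atoms$name == hydroxyl$h, ]

  old_group_sum <- sum(atoms$charge[atoms$name %in% c(methyl$carbon,
                                                      methyl$hydrogens)])
  new_unadjusted <- sum(atoms$charge[atoms$name %in% c(methyl$carbon, h_keep)]) +
    o_row$charge + h_row$charge
  shift <- (old_group_sum - new_unadjusted) / 3
  adjusted <- setNames(
    atoms$charge[match(c(methyl$carbon, h_keep), atoms$name)] + shift,
    c(methyl$carbon, h_keep))

  added <- data.frame(
    name = hydroxyl_names,
    type = c(o_row$type, h_row$type),   # LJ types copied from serine wholesale
    charge = c(o_row$charge, h_row$charge),
    lj_epsilon = c(o_row$lj_epsilon, h_row$lj_epsilon),
    lj_rmin_half = c(o_row$lj_rmin_half, h_row$lj_rmin_half),
    mass = c(o_row$mass, h_row$mass),
    element = c("O", "H"),
    stringsAsFactors = FALSE)

  patch <- structure(list(
    target_residue_name = mc_residue$name,
    deleted_atoms = h_del,
    added_atoms = added,
    charge_adjustments = adjusted,
    new_bonds = rbind(c(methyl$carbon, hydroxyl_names[1]),
                      hydroxyl_names)),
    class = "flipsite_patch")

  # net charge change must vanish: deletions + additions + adjustments
  dq <- sum(added$charge) - atoms$charge[atoms$name == h_del] +
    sum(adjusted - atoms$charge[match(names(adjusted), atoms$name)])
  stopifnot(abs(dq) < 1e-12)
  patch
}

find_methyl <- function(residue) {
  atoms <- residue$atoms
  elem <- substr(atoms$name, 1, 1)      # RTF names lead with the element
  bonds <- residue$bonds
  if (nrow(bonds) == 0) return(NULL)
  for (c_name in atoms$name[elem == "C"]) {
    partners <- c(bonds[bonds[, 1] == c_name, 2],
                  bonds[bonds[, 2] == c_name, 1])
    hs <- partners[substr(partners, 1, 1) == "H"]
    hs <- hs[hs %in% atoms$name]
    if (length(hs) == 3)
      return(list(carbon = c_name,
                  hydrogens = hs[order(match(hs, atoms$name))]))
  }
  NULL
}

find_hydroxyl <- function(residue) {
  atoms <- residue$atoms
  bonds <- residue$bonds
  if (nrow(bonds) == 0) return(NULL)
  for (o_name in atoms$name[substr(atoms$name, 1, 1) == "O"]) {
    partners <- c(bonds[bonds[, 1] == o_name, 2],
                  bonds[bonds[, 2] == o_name, 1])
    hs <- partners[substr(partners, 1, 1) == "H"]
    hs <- hs[hs %in% atoms$name]
    if (length(hs) == 1) return(list(o = o_name, h = hs))
  }
  NULL
}

#' @export
print.flipsite_patch <- function(x, ...) {
  cat(sprintf("<flipsite_patch> %s: -%s +%s; %d charges adjusted\n",
              x$target_residue_name, paste(x$deleted_atoms, collapse = ","),
              paste(x$added_atoms$name, collapse = ","),
              length(x$charge_adjustments)))
  invisible(x)
}

#' Apply a residue patch to a topology in memory
#'
#' Deletes the patch's atoms from the addressed residue, appends the added
#' atoms at the end of that residue's block, rewrites charges per the
#' patch's adjustments, and updates the bond list. Atom order outside the
#' residue and all untouched residues are preserved bit-identically.
#'
#' Coordinates are not handled here: patching is a parameter-level edit,
#' so frames read alongside the original topology no longer match the
#' patched one (the added atoms have no positions until a structure is
#' rebuilt).
#'
#' @param topology a [topology()]
#' @param chain,residue_id address of the residue to patch
#' @param patch a [build_5hmc_patch()] result
#' @return a new [topology()]
#' @export
apply_patch <- function(topology, chain, residue_id, patch) {
  res <- residue_table(topology)
  r <- which(res$chain == chain & res$residue_id == residue_id)
  if (length(r) != 1)
    stop("residue ", chain, ":", residue_id, " not found in topology")
  if (res$residue_name[r] != patch$target_residue_name)
    stop("residue ", chain, ":", residue_id, " is ", res$residue_name[r],
         ", but the patch targets ", patch$target_residue_name)
  idx <- res$first_atom[r]:res$last_atom[r]
  a <- topology$atoms

  del_local <- match(patch$deleted_atoms, a$name[idx])
  if (anyNA(del_local))
    stop("patch deletes atom(s) absent from the residue: ",
         paste(patch$deleted_atoms[is.na(del_local)], collapse = ", "),
         " (already patched?)")
  del_global <- idx[del_local]

  # charge adjustments address existing atoms by name
  adj_local <- match(names(patch$charge_adjustments), a$name[idx])
  if (anyNA(adj_local))
    stop("patch adjusts charge of absent atom(s): ",
         paste(names(patch$charge_adjustments)[is.na(adj_local)],
               collapse = ", "))
  a$charge[idx[adj_local]] <- unname(patch$charge_adjustments)

  add <- patch$added_atoms
  if (nrow(add) > 0 && any(add$name %in% a$name[setdiff(idx, del_global)]))
    stop("patch adds atom name(s) already present in the residue",
         " (already patched?)")
  add_df <- if (nrow(add) == 0) a[0, , drop = FALSE] else data.frame(
    name = add$name, element = add$element,
    residue_name = a$residue_name[idx[1]], residue_id = a$residue_id[idx[1]],
    chain = a$chain[idx[1]],
    charge = add$charge, lj_epsilon = add$lj_epsilon,
    lj_rmin_half = add$lj_rmin_half, mass = add$mass,
    is_donor = FALSE, is_hydrogen = add$element == "H",
    is_acceptor = add$element %in% c("O", "N"), is_water = FALSE,
    stringsAsFactors = FALSE)

  keep <- setdiff(seq_len(nrow(a)), del_global)
  insert_after <- res$last_atom[r]
  pre <- keep[keep <= insert_after]
  post <- keep[keep > insert_after]
  new_atoms <- rbind(a[pre, , drop = FALSE], add_df, a[post, , drop = FALSE])
  rownames(new_atoms) <- NULL

  # old index -> new index map (deleted atoms map to NA)
  remap <- rep(NA_integer_, nrow(a))
  remap[pre] <- seq_along(pre)
  remap[post] <- length(pre) + nrow(add_df) + seq_along(post)

  bonds <- topology$bonds
  if (nrow(bonds) > 0) {
    touches_deleted <- bonds[, 1] %in% del_global | bonds[, 2] %in% del_global
    # a deleted atom may only take bonds that tie it to the residue itself
    orphan <- touches_deleted &
      !(bonds[, 1] %in% idx & bonds[, 2] %in% idx)
    if (any(orphan))
      stop("deleting atom(s) would leave a dangling inter-residue bond")
    bonds <- bonds[!touches_deleted, , drop = FALSE]
    bonds <- cbind(remap[bonds[, 1]], remap[bonds[, 2]])
  }
  name_to_new <- function(nm) {
    hit_add <- match(nm, add$name)
    out <- length(pre) + hit_add
    local <- match(nm, a$name[idx])
    out[is.na(hit_add)] <- remap[idx[local[is.na(hit_add)]]]
    if (anyNA(out))
      stop("patch bond references unknown atom name: ",
           paste(nm[is.na(out)], collapse = ", "))
    out
  }
  if (nrow(patch$new_bonds) > 0) {
    nb <- cbind(name_to_new(patch$new_bonds[, 1]),
                name_to_new(patch$new_bonds[, 2]))
    bonds <- rbind(bonds, nb)
  }
  topology(new_atoms, bonds)
}

#' Format a patch as a CHARMM-RTF PRES block
#'
#' @param patch a [build_5hmc_patch()] result
#' @param name patch block name
#' @return character lines
#' @export
format_patch_rtf <- function(patch, name = "5HMC") {
  total_delta <- 0  # by construction the patch is charge-neutral
  lines <- c(
    sprintf("PRES %s %9.5f ! hydroxyl substitution on %s", name,
            total_delta, patch$target_residue_name),
    sprintf("DELE ATOM %s", patch$deleted_atoms),
    sprintf("ATOM %-5s %-5s %9.5f", patch$added_atoms$name,
            ifelse(is.na(patch$added_atoms$type), "X",
                   patch$added_atoms$type),
            patch$added_atoms$charge),
    sprintf("ATOM %-5s %-5s %9.5f ! adjusted",
            names(patch$charge_adjustments), "X",
            unname(patch$charge_adjustments)),
    sprintf("BOND %s %s", patch$new_bonds[, 1], patch$new_bonds[, 2]))
  lines
}
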