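#' Read a CHARMM-style residue topology (RTF dialect)
#'
#' Supported records, one per line, case-insensitive keywords:
#' \describe{
#'   \item{`RESI name charge` / `PRES name charge`}{opens a residue or
#'     patch block}
#'   \item{`ATOM name type charge [epsilon rmin2 [mass]]`}{atom entry;
#'     `epsilon` (kcal/mol, magnitude) and `rmin2` (Rmin/2, Angstrom) are a
#'     dialect extension carrying the Lennard-Jones parameters that CHARMM
#'     keeps in a separate parameter file}
#'   \item{`BOND a b [c d ...]`}{pairs of bonded atom names}
#'   \item{`DONO h d`}{hydrogen-bond donor: hydrogen atom name, then the
#'     heavy donor atom name}
#'   \item{`ACCE a [antecedent]`}{hydrogen-bond acceptor atom name}
#'   \item{`GROUP`, `MASS`, `DELE`, comments (`!`, `*`)}{tolerated}
#' }
#'
#' @param rtf_text character lines, one string with newlines, or file path
#' @return object of class `flipsite_rtf`: a named list of residue blocks,
#'   each with `name`, `kind` ("RESI" or "PRES"), `declared_charge`,
#'   `atoms` (data.frame `name`, `type`, `charge`, `lj_epsilon`,
#'   `lj_rmin_half`, `mass`), `bonds` (2-column character matrix),
#'   `donors` (data.frame `hydrogen`, `heavy`), `acceptors` (character)
#' @export
read_charge_topology <- function(rtf_text) {
  lines <- as_text_lines(rtf_text)
  lines <- sub("!.*$", "", lines)              # strip trailing comments
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "*")]

  residues <- list()
  cur <- NULL
  flush <- function(res, out) {
    if (is.null(res)) return(out)
    res$atoms <- do.call(rbind, res$atoms)
    if (is.null(res$atoms))
      res$atoms <- data.frame(name = character(), type = character(),
                              charge = numeric(), lj_epsilon = numeric(),
                              lj_rmin_half = numeric(), mass = numeric(),
                              stringsAsFactors = FALSE)
    if (anyDuplicated(res$atoms$name))
      stop("duplicate atom name '",
           res$atoms$name[duplicated(res$atoms$name)][1],
           "' in residue ", res$name)
    res$bonds <- if (length(res$bonds)) do.call(rbind, res$bonds) else
      matrix(character(), ncol = 2)
    res$donors <- if (length(res$donors)) do.call(rbind, res$donors) else
      data.frame(hydrogen = character(), heavy = character(),
                 stringsAsFactors = FALSE)
    out[[res$name]] <- res
    out
  }

  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "[[:space:]]+")[[1]]
    key <- toupper(substr(tok[1], 1, 4))
    if (key %in% c("RESI", "PRES")) {
      residues <- flush(cur, residues)
      cur <- list(name = tok[2], kind = key,
                  declared_charge = suppressWarnings(as.numeric(tok[3])),
                  atoms = list(), bonds = list(),
                  donors = list(), acceptors = character())
    } else if (is.null(cur)) {
      next  # header material (MASS lines etc.)
    } else if (key == "ATOM") {
      if (length(tok) < 3) stop("short ATOM line ", i, ": '", lines[i], "'")
      # CHARMM order is `ATOM name type charge`; a typeless
      # `ATOM name charge` short form is also accepted
      has_type <- is.na(suppressWarnings(as.numeric(tok[3])))
      qpos <- if (has_type) 4L else 3L
      if (length(tok) < qpos)
        stop("missing charge on ATOM line ", i, " of residue ", cur$name)
      q <- suppressWarnings(as.numeric(tok[qpos]))
      if (is.na(q))
        stop("non-numeric charge '", tok[qpos], "' on ATOM line ", i,
             " of residue ", cur$name)
      num_or_na <- function(k) if (length(tok) >= k)
        suppressWarnings(as.numeric(tok[k])) else NA_real_
      eps <- num_or_na(qpos + 1L)
      if (!is.na(eps)) eps <- abs(eps)  # normalize CHARMM sign convention
      cur$atoms[[length(cur$atoms) + 1L]] <- data.frame(
        name = tok[2], type = if (has_type) tok[3] else NA_character_,
        charge = q, lj_epsilon = eps, lj_rmin_half = num_or_na(qpos + 2L),
        mass = num_or_na(qpos + 3L), stringsAsFactors = FALSE)
    } else if (key == "BOND" || key == "DOUB") {
      nm <- tok[-1]
      if (length(nm) %% 2 != 0)
        stop("odd number of atom names on BOND line ", i)
      for (j in seq(1, length(nm), by = 2))
        cur$bonds[[length(cur$bonds) + 1L]] <- nm[j:(j + 1)]
    } else if (key == "DONO") {
      cur$donors[[length(cur$donors) + 1L]] <- data.frame(
        hydrogen = tok[2], heavy = if (length(tok) >= 3) tok[3] else NA,
        stringsAsFactors = FALSE)
    } else if (key == "ACCE") {
      cur$acceptors <- c(cur$acceptors, tok[2])
    }
    # GROUP / DELE / IC / ANGL / DIHE / IMPR lines tolerated silently
  }
  residues <- flush(cur, residues)
  structure(residues, class = "flipsite_rtf")
}

#' @export
print.flipsite_rtf <- function(x, ...) {
  cat(sprintf("<flipsite_rtf> %d residue blocks: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}

#' Net charge of an RTF residue block
#' @param residue one element of a [read_charge_topology()] result
#' @export
residue_net_charge <- function(residue) sum(residue$atoms$charge)

#' Merge RTF charges, parameters and roles onto a structure topology
#'
#' Looks up every residue of `topology` by `residue_name` in `rtf` and
#' assigns per-atom charge, Lennard-Jones parameters and mass by atom
#' name. Donor/acceptor annotations (`DONO`/`ACCE`) become atom roles;
#' atoms with element `H` get the hydrogen role. Intra-residue `BOND`
#' records are added to the topology bond list (by name, within each
#' residue instance); inter-residue connectivity (`+`/`-` prefixed names)
#' is ignored. Atom order is never changed.
#'
#' @param topology a [topology()] (e.g. from [read_structure()])
#' @param rtf a [read_charge_topology()] result
#' @return a new [topology()] with parameters and roles assigned
#' @export
merge_charge_topology <- function(topology, rtf) {
  a <- topology$atoms
  res <- residue_table(topology)
  bonds <- list(topology$bonds)
  for (r in seq_len(nrow(res))) {
    block <- rtf[[res$residue_name[r]]]
    if (is.null(block))
      stop("residue ", res$residue_name[r], " (", res$chain[r], res$residue_id[r],
           ") not found in charge topology")
    idx <- res$first_atom[r]:res$last_atom[r]
    pos <- match(a$name[idx], block$atoms$name)
    if (anyNA(pos))
      stop("atom ", a$name[idx][which(is.na(pos))[1]], " of residue ",
           res$residue_name[r], " ", res$residue_id[r],
           " has no entry in the charge topology")
    a$charge[idx] <- block$atoms$charge[pos]
    a$lj_epsilon[idx] <- block$atoms$lj_epsilon[pos]
    a$lj_rmin_half[idx] <- block$atoms$lj_rmin_half[pos]
    a$mass[idx] <- block$atoms$mass[pos]
    a$is_donor[idx] <- a$name[idx] %in% block$donors$heavy
    a$is_acceptor[idx] <- a$name[idx] %in% block$acceptors
    a$is_hydrogen[idx] <- a$element[idx] == "H" |
      a$name[idx] %in% block$donors$hydrogen
    if (nrow(block$bonds) > 0) {
      intra <- !grepl("^[+-]", block$bonds[, 1]) &
               !grepl("^[+-]", block$bonds[, 2])
      b1 <- idx[match(block$bonds[intra, 1], a$name[idx])]
      b2 <- idx[match(block$bonds[intra, 2], a$name[idx])]
      ok <- !is.na(b1) & !is.na(b2)
      if (any(ok)) bonds[[length(bonds) + 1L]] <- cbind(b1[ok], b2[ok])
    }
  }
  if (anyNA(a$charge)) stop("unassigned charges remain after merge")
  bonds <- unique(do.call(rbind, bonds))
  topology(a, bonds)
}
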