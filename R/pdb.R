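#' Read a PDB structure into a topology and coordinate frames
#'
#' Parses `ATOM`/`HETATM` records (fixed-width columns) with optional
#' `MODEL`/`ENDMDL` blocks. All models must contain the same atoms; each
#' model becomes one coordinate frame over a single shared topology.
#'
#' Charges, Lennard-Jones parameters and donor/acceptor roles are left
#' unset (`NA`/`FALSE`); merge them from a CHARMM-style residue topology
#' with [merge_charge_topology()]. Water residues (`HOH`, `TIP3`, `WAT`,
#' `SPC`, `SOL`) are flagged `is_water` on ingest. Unicode prime characters
#' in atom names (as in U+2032) are normalized to the ASCII apostrophe,
#' with a message recording the mapping, since deposited files vary.
#'
#' Residue ids are taken verbatim from the `resSeq` column; atom order is
#' file order.
#'
#' @param pdb_text character vector of lines, a single string with
#'   embedded newlines, or a path to an existing file
#' @return list with elements `topology` (a [topology()]) and `frames`
#'   (list of [frame()] objects, one per MODEL; length 1 for a plain file)
#' @export
read_structure <- function(pdb_text) {
  lines <- as_text_lines(pdb_text)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM") |
    substr(lines, 1, 5) == "ATOM " | substr(lines, 1, 6) == "HETATM"
  is_model_open <- startsWith(lines, "MODEL")
  is_model_close <- startsWith(lines, "ENDMDL")

  if (!any(is_atom)) stop("no ATOM/HETATM records found: empty input")

  model_id <- cumsum(is_model_open)
  has_models <- any(is_model_open)
  atom_lines <- which(is_atom)
  atom_model <- if (has_models) model_id[atom_lines] else rep(1L, length(atom_lines))
  if (has_models && any(atom_model == 0L))
    stop("ATOM record before first MODEL in a multi-model file (line ",
         atom_lines[atom_model == 0L][1], ")")

  parse_block <- function(idx) {
    ln <- lines[idx]
    field <- function(from, to) substr(ln, from, to)
    num_field <- function(from, to, what) {
      raw <- field(from, to)
      v <- suppressWarnings(as.numeric(raw))
      bad <- which(is.na(v) & trimws(raw) != "")
      bad2 <- which(trimws(raw) == "")
      bad <- sort(c(bad, bad2))
      if (length(bad) > 0)
        stop("malformed ", what, " field in PDB record at line ",
             idx[bad[1]], ": '", raw[bad[1]], "'")
      v
    }
    name <- trimws(field(13, 16))
    primes <- grepl("\u2032", name)
    if (any(primes)) {
      message("normalized unicode prime to ASCII apostrophe in atom names: ",
              paste(unique(name[primes]), collapse = ", "))
      name <- gsub("\u2032", "'", name)
    }
    elem <- trimws(field(77, 78))
    guess <- toupper(substr(gsub("[^A-Za-z].*$", "", gsub("^[0-9]*", "", name)), 1, 1))
    elem <- ifelse(elem == "", guess, elem)
    data.frame(
      name = name,
      element = elem,
      residue_name = trimws(field(18, 21)),
      residue_id = {
        raw <- field(23, 26)
        v <- suppressWarnings(as.integer(raw))
        if (any(is.na(v)))
          stop("malformed residue number in PDB record at line ",
               idx[which(is.na(v))[1]], ": '", raw[which(is.na(v))[1]], "'")
        v
      },
      chain = trimws(field(22, 22)),
      x = num_field(31, 38, "x-coordinate"),
      y = num_field(39, 46, "y-coordinate"),
      z = num_field(47, 54, "z-coordinate"),
      stringsAsFactors = FALSE
    )
  }

  first_model <- atom_lines[atom_model == atom_model[1]]
  tab <- parse_block(first_model)
  water_names <- c("HOH", "TIP3", "WAT", "SPC", "SOL", "TIP3P")
  atoms <- data.frame(
    name = tab$name, element = tab$element,
    residue_name = tab$residue_name, residue_id = tab$residue_id,
    chain = tab$chain,
    charge = NA_real_, lj_epsilon = NA_real_, lj_rmin_half = NA_real_,
    mass = NA_real_,
    is_donor = FALSE, is_hydrogen = FALSE, is_acceptor = FALSE,
    is_water = tab$residue_name %in% water_names,
    stringsAsFactors = FALSE
  )
  top <- topology(atoms)

  models <- unique(atom_model)
  frames <- vector("list", length(models))
  for (k in seq_along(models)) {
    idx <- atom_lines[atom_model == models[k]]
    blk <- if (k == 1) tab else parse_block(idx)
    if (nrow(blk) != nrow(tab) || !identical(blk$name, tab$name))
      stop("MODEL ", k, " does not contain the same atoms as MODEL 1")
    frames[[k]] <- frame(cbind(blk$x, blk$y, blk$z), time = k - 1)
  }
  list(topology = top, frames = frames)
}

#' Write a topology plus frames as (multi-model) PDB text
#'
#' @param topology a [topology()]
#' @param frames a single [frame()] or list of frames; more than one frame
#'   produces `MODEL`/`ENDMDL` blocks
#' @return character vector of PDB lines
#' @export
write_structure <- function(topology, frames) {
  if (inherits(frames, "flipsite_frame")) frames <- list(frames)
  a <- topology$atoms
  fmt_one <- function(fr) {
    xyz <- fr$coordinates
    if (nrow(xyz) != nrow(a))
      stop("frame atom count (", nrow(xyz), ") does not match topology (",
           nrow(a), ")")
    nm <- ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name)
    sprintf("%-6s%5d %-4s %-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            ifelse(a$is_water, "HETATM", "ATOM"),
            seq_len(nrow(a)) %% 100000L, nm, a$residue_name, a$chain,
            a$residue_id, xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, a$element)
  }
  if (length(frames) == 1L) {
    c(fmt_one(frames[[1]]), "END")
  } else {
    out <- character(0)
    for (k in seq_along(frames)) {
      out <- c(out, sprintf("MODEL %8d", k), fmt_one(frames[[k]]), "ENDMDL")
    }
    c(out, "END")
  }
}

# Accept a file path, a single embedded-newline string, or a line vector.
as_text_lines <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    return(readLines(x, warn = FALSE))
  }
  if (length(x) == 1 && grepl("\n", x)) {
    return(strsplit(x, "\n", fixed = TRUE)[[1]])
  }
  as.character(x)
}
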