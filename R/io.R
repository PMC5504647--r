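# Readers and writers: minimal PDB complexes, multi-model conformer
# libraries, key-value run configuration, delimited archive/diagnostic
# tables.

#' Read a receptor-ligand complex from a PDB file
#'
#' `ATOM` records form the receptor, `HETATM` records the ligand; waters
#' (residue `HOH`) are dropped.  Receptor atoms named `N`, `CA`, `C`, `O`
#' are flagged as backbone (anything else, including `CB`, as side
#' chain; `CB` still enters the coarse-grained clash test by name).
#' Parsing is done with `bio3d::read.pdb()` after a light format check.
#'
#' @param path PDB file path.
#' @return list with `receptor` and `ligand` atom tables
#'   ([atom_records()]).
#' @export
read_pdb_complex <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(rec)) {
    flds <- substring(lines[i], c(31, 39, 47), c(38, 46, 54))
    if (anyNA(suppressWarnings(as.numeric(flds))))
      stop("malformed coordinate fields at line ", i, " of ", path)
  }
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  elem <- ifelse(!is.na(at$elesy) & nzchar(trimws(at$elesy)),
                 trimws(at$elesy), substr(trimws(at$elety), 1, 1))
  is_rec <- at$type == "ATOM"
  is_lig <- at$type == "HETATM" & at$resid != "HOH"
  if (!any(is_lig)) stop("no ligand HETATM records in ", path)
  role <- ifelse(trimws(at$elety) %in% c("N", "CA", "C", "O"),
                 "receptor-backbone", "receptor-sidechain")
  receptor <- atom_records(at$x[is_rec], at$y[is_rec], at$z[is_rec],
                           element = elem[is_rec],
                           name = trimws(at$elety[is_rec]),
                           role = role[is_rec])
  ligand <- atom_records(at$x[is_lig], at$y[is_lig], at$z[is_lig],
                         element = elem[is_lig],
                         name = trimws(at$elety[is_lig]), role = "ligand")
  list(receptor = receptor, ligand = ligand)
}

.pdb_atom_line <- function(record, serial, name, resname, chain, resno,
                           xyz, element) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, substr(name, 1, 4), "", resname, chain, resno, "",
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, element)
}

.pose_pdb_lines <- function(pose) {
  rec <- pose$receptor
  n_rec <- nrow(rec)
  lines <- character(0)
  for (i in seq_len(n_rec)) {
    lines <- c(lines, .pdb_atom_line("ATOM", i, rec$name[i], "ALA", "A",
                                     i, c(rec$x[i], rec$y[i], rec$z[i]),
                                     rec$element[i]))
  }
  lig <- ligand_coords(pose)
  for (j in seq_len(nrow(lig))) {
    lines <- c(lines, .pdb_atom_line("HETATM", n_rec + j,
                                     paste0(pose$lig_elements[j], j),
                                     "LIG", "X", 1, lig[j, ],
                                     pose$lig_elements[j]))
  }
  lines
}

#' Write pose(s) as a PDB file
#'
#' Standard fixed-width PDB, coordinates to three decimals, serial
#' numbers 1-based and contiguous; a list of poses is written as
#' `MODEL`/`ENDMDL` blocks.
#'
#' @param poses a [new_pose()] or a list of poses.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb_complex <- function(poses, path) {
  if (inherits(poses, "dock_pose")) {
    lines <- c(.pose_pdb_lines(poses), "END")
  } else {
    lines <- character(0)
    for (m in seq_along(poses)) {
      lines <- c(lines, sprintf("MODEL     %4d", m),
                 .pose_pdb_lines(poses[[m]]), "ENDMDL")
    }
    lines <- c(lines, "END")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write a ligand conformer library as a multi-model PDB
#' @param conformers list of local coordinate matrices.
#' @param elements ligand element symbols.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conformers_pdb <- function(conformers, elements, path) {
  lines <- character(0)
  for (m in seq_along(conformers)) {
    lines <- c(lines, sprintf("MODEL     %4d", m))
    cf <- conformers[[m]]
    for (j in seq_len(nrow(cf))) {
      lines <- c(lines, .pdb_atom_line("HETATM", j, paste0(elements[j], j),
                                       "LIG", "X", 1, cf[j, ], elements[j]))
    }
    lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Read a ligand conformer library from a multi-model PDB
#' @param path file path.
#' @return list with `conformers` (coordinate matrices, centred as read)
#'   and `elements`.
#' @export
read_conformers_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL", lines)
  blocks <- if (length(model_starts) == 0L) list(lines) else {
    ends <- grep("^ENDMDL", lines)
    mapply(function(s, e) lines[(s + 1):(e - 1)], model_starts, ends,
           SIMPLIFY = FALSE)
  }
  conformers <- list()
  elements <- NULL
  for (b in blocks) {
    het <- b[grepl("^HETATM", b)]
    if (!length(het)) next
    xyz <- cbind(as.numeric(substring(het, 31, 38)),
                 as.numeric(substring(het, 39, 46)),
                 as.numeric(substring(het, 47, 54)))
    el <- trimws(substring(het, 77, 78))
    empty <- !nzchar(el)
    if (any(empty)) el[empty] <- substr(trimws(substring(het, 13, 16)), 1, 1)[empty]
    conformers[[length(conformers) + 1L]] <- xyz
    if (is.null(elements)) elements <- el
  }
  if (!length(conformers)) stop("no HETATM conformers in ", path)
  list(conformers = conformers, elements = elements)
}

#' Assemble / read / write a run configuration
#'
#' A run configuration bundles the [sampler_config()], [move_config()]
#' and the score-weight preset; it round-trips losslessly through a YAML
#' key-value file.
#'
#' @param sampler a [sampler_config()].
#' @param moves a [move_config()].
#' @param weights_preset `"hard"` or `"soft"`.
#' @return a list of class `run_config`.
#' @export
run_config <- function(sampler = sampler_config(), moves = move_config(),
                       weights_preset = "hard") {
  structure(list(sampler = sampler, moves = moves,
                 weights_preset = weights_preset), class = "run_config")
}

#' @rdname run_config
#' @param path config file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(list(sampler = unclass(config$sampler),
                        moves = unclass(config$moves),
                        weights_preset = config$weights_preset), path)
  invisible(path)
}

#' @rdname run_config
#' @param config a `run_config` (for writing).
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  run_config(sampler = do.call(sampler_config, y$sampler),
             moves = do.call(move_config, y$moves),
             weights_preset = y$weights_preset %||% "hard")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a sampling archive as a delimited table
#'
#' Tab-separated columns `(cycle, step, replica, temperature, tscore,
#' ifdelta, accepted, selected)` preceded by `#`-prefixed provenance
#' header lines (package version, seed, full configuration) sufficient to
#' reproduce the run.
#'
#' @param result an `mc_result` or `remc_result`.
#' @param path output path.
#' @param ifdelta optional per-entry interface deltas (else `NA`).
#' @param config optional [run_config()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_archive_table <- function(result, path, ifdelta = NULL, config = NULL) {
  df <- archive_table(result$archive)
  df$ifdelta <- if (is.null(ifdelta)) NA_real_ else ifdelta
  df <- df[, c("cycle", "step", "replica", "temperature", "tscore",
               "ifdelta", "accepted", "selected")]
  # no timestamp: identical runs must produce byte-identical files
  hdr <- paste0("# remcdock ", as.character(utils::packageVersion("remcdock")))
  if (!is.null(config)) {
    flat <- c(unlist(unclass(config$sampler)), unlist(unclass(config$moves)),
              weights_preset = config$weights_preset)
    hdr <- c(hdr, paste0("# config ", names(flat), " = ", as.character(flat)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a delimited archive table
#' @param path file written by [write_archive_table()].
#' @return a data frame (header lines skipped).
#' @export
read_archive_table <- function(path) {
  read.delim(path, comment.char = "#")
}
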