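#' Construct a Frame
#'
#' @param coords N x 3 numeric matrix of Calpha positions (Angstrom).
#' @param residueIndex 1-based residue numbers (default 1..N).
#' @param residueName 3-letter codes (default "ALA").
#' @param element element symbols (default "C": the alpha carbon).
#' @param timeNs snapshot time in ns.
#' @param replicaId replica label.
#' @return A [Frame-class] object.
#' @export
Frame <- function(coords, residueIndex = seq_len(nrow(coords)),
                  residueName = rep("ALA", nrow(coords)),
                  element = rep("C", nrow(coords)),
                  timeNs = 0, replicaId = 1L) {
  new("Frame", coords = as.matrix(coords), residueIndex = as.integer(residueIndex),
      residueName = residueName, element = element,
      timeNs = as.numeric(timeNs), replicaId = as.integer(replicaId))
}

#' Construct a Trajectory
#'
#' @param coords n_frames x n_residues x 3 array (Angstrom).
#' @param residueIndex,residueName,element per-residue annotation.
#' @param replicaId per-frame replica labels (default all 1).
#' @param timeNs per-frame times; default 0, interval, 2*interval, ... within
#'   each replica.
#' @param snapshotIntervalNs snapshot spacing (ns).
#' @param aligned provenance flag.
#' @param referenceLabel provenance of the alignment reference.
#' @return A [Trajectory-class] object.
#' @export
Trajectory <- function(coords, residueIndex = seq_len(dim(coords)[2]),
                       residueName = rep("ALA", dim(coords)[2]),
                       element = rep("C", dim(coords)[2]),
                       replicaId = rep(1L, dim(coords)[1]),
                       timeNs = NULL, snapshotIntervalNs = 1,
                       aligned = FALSE, referenceLabel = NA_character_) {
  nf <- dim(coords)[1]
  replicaId <- as.integer(replicaId)
  if (is.null(timeNs)) {
    timeNs <- unlist(lapply(split(seq_len(nf), replicaId), function(ix) {
      (seq_along(ix) - 1) * snapshotIntervalNs
    }), use.names = FALSE)
  }
  new("Trajectory", coords = coords, residueIndex = as.integer(residueIndex),
      residueName = residueName, element = element, replicaId = replicaId,
      timeNs = as.numeric(timeNs), snapshotIntervalNs = snapshotIntervalNs,
      aligned = aligned, referenceLabel = referenceLabel)
}

#' @describeIn Trajectory number of frames
#' @param x a Trajectory
#' @export
setMethod("nFrames", "Trajectory", function(x) dim(x@coords)[1])

#' @describeIn Trajectory number of residues
#' @export
setMethod("nResidues", "Trajectory", function(x) dim(x@coords)[2])

#' @describeIn Trajectory residue indices
#' @export
setMethod("residueIndex", "Trajectory", function(x) x@residueIndex)

#' @describeIn Trajectory per-frame replica labels
#' @export
setMethod("replicaId", "Trajectory", function(x) x@replicaId)

#' @describeIn Trajectory per-frame snapshot times (ns)
#' @export
setMethod("timeNs", "Trajectory", function(x) x@timeNs)

#' @describeIn Trajectory alignment provenance flag
#' @export
setMethod("isAligned", "Trajectory", function(x) x@aligned)

#' @describeIn Trajectory frame (replica, time) labels
#' @export
setMethod("frameLabels", "Trajectory", function(x) {
  data.frame(replica_id = x@replicaId, time_ns = x@timeNs)
})

setMethod("nResidues", "Frame", function(x) nrow(x@coords))
setMethod("residueIndex", "Frame", function(x) x@residueIndex)

#' @describeIn Trajectory extract frame i (1-based position; the global report
#'   index is i - 1)
#' @param i frame position
#' @export
setMethod("getFrame", "Trajectory", function(x, i) {
  stopifnot(i >= 1, i <= nFrames(x))
  Frame(x@coords[i, , , drop = TRUE], residueIndex = x@residueIndex,
        residueName = x@residueName, element = x@element,
        timeNs = x@timeNs[i], replicaId = x@replicaId[i])
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", nFrames(object), "frames x", nResidues(object),
      "residues (Calpha)\n")
  cat("  replicas:", paste(unique(object@replicaId), collapse = ", "),
      "| snapshot interval:", object@snapshotIntervalNs, "ns\n")
  cat("  aligned:", object@aligned,
      if (!is.na(object@referenceLabel)) paste0("(", object@referenceLabel, ")") else "",
      "\n")
})

setMethod("show", "Frame", function(object) {
  cat("Frame:", nrow(object@coords), "Calpha atoms, replica",
      object@replicaId, "at", object@timeNs, "ns\n")
})

## ---- multi-model PDB I/O -------------------------------------------------

#' Read a multi-model PDB file as a Trajectory
#'
#' Each MODEL/ENDMDL block becomes one frame, in file order. Only Calpha atoms
#' are retained; every model must contain exactly the residue set of the first
#' model. Alternate locations other than blank or 'A' are ignored; insertion
#' codes are rejected (simulation snapshots do not carry them). Frame labels
#' written by [writeMultimodelPDB()] (REMARK 250 lines) are recovered when
#' present; otherwise frames get replica 1 and times 0, interval, 2*interval.
#'
#' @param path PDB file path.
#' @param snapshotIntervalNs fallback snapshot spacing when the file carries no
#'   frame labels.
#' @return A [Trajectory-class].
#' @export
readMultimodelPDB <- function(path, snapshotIntervalNs = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  rec <- substr(lines, 1, 6)
  model_starts <- which(trimws(rec) == "MODEL")
  model_ends <- which(trimws(rec) == "ENDMDL")
  if (length(model_starts) == 0L) {
    ## single-model file: treat the whole file as one block
    model_starts <- 0L
    model_ends <- length(lines) + 1L
  }
  if (length(model_starts) != length(model_ends))
    stop("unbalanced MODEL/ENDMDL blocks in ", path)

  parse_block <- function(b) {
    block <- lines[(model_starts[b] + 1L):(model_ends[b] - 1L)]
    atom <- block[substr(block, 1, 6) %in% c("ATOM  ", "HETATM")]
    name <- trimws(substr(atom, 13, 16))
    altloc <- substr(atom, 17, 17)
    icode <- substr(atom, 27, 27)
    ca <- name == "CA" & altloc %in% c(" ", "A")
    atom <- atom[ca]; icode <- icode[ca]
    if (any(icode != " "))
      stop("insertion codes are not supported (model ", b, ")")
    data.frame(
      residue_index = as.integer(substr(atom, 23, 26)),
      residue_name = trimws(substr(atom, 18, 20)),
      element = {
        el <- trimws(substr(atom, 77, 78))
        ifelse(el == "", "C", el)
      },
      x = as.numeric(substr(atom, 31, 38)),
      y = as.numeric(substr(atom, 39, 46)),
      z = as.numeric(substr(atom, 47, 54)),
      stringsAsFactors = FALSE
    )
  }

  first <- parse_block(1L)
  if (nrow(first) == 0L) stop("no Calpha atoms found in model 1 of ", path)
  nres <- nrow(first)
  nf <- length(model_starts)
  coords <- array(NA_real_, c(nf, nres, 3))
  for (b in seq_len(nf)) {
    blk <- parse_block(b)
    missing <- setdiff(first$residue_index, blk$residue_index)
    if (length(missing) > 0L)
      stop("structural error: model ", b, " lacks a Calpha for residue ",
           paste(missing, collapse = ", "))
    if (!identical(blk$residue_index, first$residue_index))
      stop("consistency error: model ", b,
           " has a different residue set than model 1")
    coords[b, , ] <- as.matrix(blk[, c("x", "y", "z")])
  }

  ## recover frame labels written by writeMultimodelPDB, if any
  lab <- lines[startsWith(lines, "REMARK 250 FRAME")]
  if (length(lab) == nf) {
    parts <- do.call(rbind, strsplit(trimws(sub("REMARK 250 FRAME", "", lab)), "\\s+"))
    rep_id <- as.integer(parts[, 3]); t_ns <- as.numeric(parts[, 5])
  } else {
    rep_id <- rep(1L, nf)
    t_ns <- (seq_len(nf) - 1) * snapshotIntervalNs
  }
  Trajectory(coords, residueIndex = first$residue_index,
             residueName = first$residue_name, element = first$element,
             replicaId = rep_id, timeNs = t_ns,
             snapshotIntervalNs = snapshotIntervalNs)
}

#' Write a Trajectory as a multi-model PDB file
#'
#' Standard MODEL/ENDMDL blocks with fixed-width %8.3f coordinates. Frame
#' labels are preserved in REMARK 250 lines so that
#' \code{readMultimodelPDB(writeMultimodelPDB(x))} round-trips coordinates
#' (within the 0.001 Angstrom format precision) and (replica, time) labels.
#'
#' @param traj a non-empty [Trajectory-class].
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
writeMultimodelPDB <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  if (nFrames(traj) == 0L) stop("precondition error: empty trajectory")
  if (max(abs(traj@coords)) > 9999.999)
    stop("format-overflow error: coordinate magnitude exceeds 9999.999 Angstrom")
  con <- file(path, "w")
  on.exit(close(con))
  nres <- nResidues(traj)
  for (f in seq_len(nFrames(traj))) {
    writeLines(sprintf("REMARK 250 FRAME %d REPLICA %d TIME_NS %g",
                       f - 1L, traj@replicaId[f], traj@timeNs[f]), con)
    writeLines(sprintf("MODEL     %4d", f), con)
    writeLines(sprintf(
      "ATOM  %5d  CA  %-3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %-2s",
      seq_len(nres), traj@residueName, traj@residueIndex,
      traj@coords[f, , 1], traj@coords[f, , 2], traj@coords[f, , 3],
      traj@element), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Concatenate replica trajectories
#'
#' Frames are stacked replica-by-replica in input order with 0-based global
#' indices, so the 0 ns frames of three 101-frame replicas land at global
#' indices 0, 101 and 202. Replica ids are renumbered 1..n in input order so
#' the result satisfies the (replica, time) frame ordering invariant.
#'
#' @param replicas list of [Trajectory-class] objects sharing one residue set
#'   and snapshot interval.
#' @return A single concatenated [Trajectory-class].
#' @export
concatenateReplicas <- function(replicas) {
  stopifnot(length(replicas) >= 1L)
  ref <- replicas[[1]]
  for (i in seq_along(replicas)) {
    if (nResidues(replicas[[i]]) != nResidues(ref) ||
        !identical(residueIndex(replicas[[i]]), residueIndex(ref)))
      stop("consistency error: replica ", i,
           " has a different residue set than replica 1")
    if (replicas[[i]]@snapshotIntervalNs != ref@snapshotIntervalNs)
      stop("consistency error: replica ", i, " has a different snapshot interval")
  }
  if (length(replicas) == 1L) return(ref)
  nf <- vapply(replicas, nFrames, integer(1))
  coords <- array(NA_real_, c(sum(nf), nResidues(ref), 3))
  rep_id <- integer(0); t_ns <- numeric(0)
  at <- 0L
  for (i in seq_along(replicas)) {
    coords[at + seq_len(nf[i]), , ] <- replicas[[i]]@coords
    rep_id <- c(rep_id, rep(i, nf[i]))
    t_ns <- c(t_ns, replicas[[i]]@timeNs)
    at <- at + nf[i]
  }
  Trajectory(coords, residueIndex = residueIndex(ref),
             residueName = ref@residueName, element = ref@element,
             replicaId = rep_id, timeNs = t_ns,
             snapshotIntervalNs = ref@snapshotIntervalNs,
             aligned = all(vapply(replicas, isAligned, logical(1))))
}
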