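#' Number of frames in a trajectory-like object
#' @param x object
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Number of residues in a trajectory-like object
#' @param x object
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Residue indices of an object
#' @param x object
#' @export
setGeneric("residueIndex", function(x) standardGeneric("residueIndex"))

#' Per-frame replica labels
#' @param x object
#' @export
setGeneric("replicaId", function(x) standardGeneric("replicaId"))

#' Per-frame snapshot times (ns)
#' @param x object
#' @export
setGeneric("timeNs", function(x) standardGeneric("timeNs"))

#' Has the object been superposed onto a reference?
#' @param x object
#' @export
setGeneric("isAligned", function(x) standardGeneric("isAligned"))

#' Extract one Frame from a Trajectory
#' @param x a [Trajectory-class]
#' @param i 1-based frame position
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))

#' Frame (replica, time) labels as a data.frame
#' @param x object
#' @export
setGeneric("frameLabels", function(x) standardGeneric("frameLabels"))
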