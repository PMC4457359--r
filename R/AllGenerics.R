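## Generics and accessors.  Slots are reached through these, never directly.

#' @name accessors
#' @title Accessors for model objects
#' @description Small accessor generics for [ModelParams-class],
#'   [LandscapeConstants-class], [TrajectoryEnsemble-class],
#'   [PIResult-class] and [RateMatrix-class] objects.
#' @param x an object.
#' @return The corresponding slot value or derived scalar.
NULL

#' @rdname accessors
#' @export
setGeneric("interfaceLength", function(x) standardGeneric("interfaceLength"))
#' @rdname accessors
#' @export
setGeneric("fitnessCurvature", function(x) standardGeneric("fitnessCurvature"))
#' @rdname accessors
#' @export
setGeneric("popSize", function(x) standardGeneric("popSize"))
#' @rdname accessors
#' @export
setGeneric("diffusionRate", function(x) standardGeneric("diffusionRate"))
#' @rdname accessors
#' @export
setGeneric("xiStar", function(x) standardGeneric("xiStar"))
#' @rdname accessors
#' @export
setGeneric("energyScale", function(x) standardGeneric("energyScale"))
#' @rdname accessors
#' @export
setGeneric("siteMutationRate", function(x) standardGeneric("siteMutationRate"))

#' @rdname accessors
#' @export
setGeneric("freeFitnessCurvature",
           function(x) standardGeneric("freeFitnessCurvature"))
#' @rdname accessors
#' @export
setGeneric("optimalBindingEnergy",
           function(x) standardGeneric("optimalBindingEnergy"))
#' @rdname accessors
#' @export
setGeneric("equilibriumWidth", function(x) standardGeneric("equilibriumWidth"))
#' @rdname accessors
#' @export
setGeneric("relaxationRate", function(x) standardGeneric("relaxationRate"))

#' @rdname accessors
#' @export
setGeneric("sampleTimes", function(x) standardGeneric("sampleTimes"))
#' @rdname accessors
#' @export
setGeneric("nReplicates", function(x) standardGeneric("nReplicates"))
#' @rdname accessors
#' @export
setGeneric("piValues", function(x) standardGeneric("piValues"))
#' @rdname accessors
#' @export
setGeneric("piStandardError", function(x) standardGeneric("piStandardError"))
#' @rdname accessors
#' @export
setGeneric("piMethod", function(x) standardGeneric("piMethod"))
#' @rdname accessors
#' @export
setGeneric("generatorMatrix", function(x) standardGeneric("generatorMatrix"))
#' @rdname accessors
#' @export
setGeneric("inviableMismatch", function(x) standardGeneric("inviableMismatch"))

#' @rdname accessors
#' @export
setMethod("interfaceLength", "ModelParams", function(x) x@ell)
#' @rdname accessors
#' @export
setMethod("fitnessCurvature", "ModelParams", function(x) x@kappaF)
#' @rdname accessors
#' @export
setMethod("popSize", "ModelParams", function(x) x@Ne)
#' @rdname accessors
#' @export
setMethod("diffusionRate", "ModelParams", function(x) x@mu)
#' @rdname accessors
#' @export
setMethod("xiStar", "ModelParams", function(x) x@xiStar)
#' @rdname accessors
#' @export
setMethod("energyScale", "ModelParams", function(x) x@epsilon)
#' @rdname accessors
#' @export
setMethod("siteMutationRate", "ModelParams", function(x) x@mu0)

#' @rdname accessors
#' @export
setMethod("freeFitnessCurvature", "LandscapeConstants", function(x) x@kappa)
#' @rdname accessors
#' @export
setMethod("optimalBindingEnergy", "LandscapeConstants", function(x) x@xi0)
#' @rdname accessors
#' @export
setMethod("equilibriumWidth", "LandscapeConstants", function(x) x@deltaXi)
#' @rdname accessors
#' @export
setMethod("relaxationRate", "LandscapeConstants", function(x) x@relaxRate)

#' @rdname accessors
#' @export
setMethod("freeFitnessCurvature", "ModelParams",
          function(x) landscapeConstants(x)@kappa)
#' @rdname accessors
#' @export
setMethod("optimalBindingEnergy", "ModelParams",
          function(x) landscapeConstants(x)@xi0)
#' @rdname accessors
#' @export
setMethod("equilibriumWidth", "ModelParams",
          function(x) landscapeConstants(x)@deltaXi)
#' @rdname accessors
#' @export
setMethod("relaxationRate", "ModelParams",
          function(x) landscapeConstants(x)@relaxRate)

#' @rdname accessors
#' @export
setMethod("sampleTimes", "TrajectoryEnsemble", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("nReplicates", "TrajectoryEnsemble", function(x) nrow(x@x1))
#' @rdname accessors
#' @export
setMethod("sampleTimes", "PIResult", function(x) x@times)
#' @rdname accessors
#' @export
setMethod("piValues", "PIResult", function(x) x@pi)
#' @rdname accessors
#' @export
setMethod("piStandardError", "PIResult", function(x) x@mcSE)
#' @rdname accessors
#' @export
setMethod("piMethod", "PIResult", function(x) x@method)
#' @rdname accessors
#' @export
setMethod("nReplicates", "PIResult", function(x) x@nReps)
#' @rdname accessors
#' @export
setMethod("generatorMatrix", "RateMatrix", function(x) x@Q)
#' @rdname accessors
#' @export
setMethod("inviableMismatch", "RateMatrix", function(x) x@rStar)
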