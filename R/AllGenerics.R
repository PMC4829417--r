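#' Accessors for network and fit objects
#'
#' `troopId`, `networkRule`, `indivIds`, `weightMatrix` and `isDirected`
#' read the corresponding slots of an [AssociationMatrix-class];
#' `socialParam` and `ilvCoefs` read a fitted [OADAFit-class].
#'
#' @param x an AssociationMatrix or OADAFit.
#' @return The slot value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("troopId", function(x) standardGeneric("troopId"))
#' @rdname accessors
#' @export
setGeneric("networkRule", function(x) standardGeneric("networkRule"))
#' @rdname accessors
#' @export
setGeneric("indivIds", function(x) standardGeneric("indivIds"))
#' @rdname accessors
#' @export
setGeneric("weightMatrix", function(x) standardGeneric("weightMatrix"))
#' @rdname accessors
#' @export
setGeneric("isDirected", function(x) standardGeneric("isDirected"))

#' @rdname accessors
#' @export
setMethod("troopId", "AssociationMatrix", function(x) x@troop)
#' @rdname accessors
#' @export
setMethod("networkRule", "AssociationMatrix", function(x) x@rule)
#' @rdname accessors
#' @export
setMethod("indivIds", "AssociationMatrix", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("weightMatrix", "AssociationMatrix", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("isDirected", "AssociationMatrix", function(x) x@directed)

#' @rdname accessors
#' @export
setGeneric("socialParam", function(x) standardGeneric("socialParam"))
#' @rdname accessors
#' @export
setMethod("socialParam", "OADAFit",
          function(x) c(unbounded = x@sUnbounded, bounded = x@sBounded))
#' @rdname accessors
#' @export
setGeneric("ilvCoefs", function(x) standardGeneric("ilvCoefs"))
#' @rdname accessors
#' @export
setMethod("ilvCoefs", "OADAFit", function(x) x@betas)

#' Symmetrize a directed association matrix
#'
#' Dyadic interactions given and received are summed so that
#' `w'(A,B) = w'(B,A) = w(A,B) + w(B,A)`. Symmetrizing an already
#' undirected matrix is a no-op with a warning.
#'
#' @param m an [AssociationMatrix-class].
#' @return An undirected AssociationMatrix (rule relabelled from
#'   `*_directed` to `*_undirected` where applicable).
#' @export
setGeneric("symmetrize", function(m) standardGeneric("symmetrize"))

#' Node strength (weighted degree)
#'
#' Sums the weighted edges each individual has with all others. For a
#' directed matrix the default convention sums edges given and received
#' (in + out); `mode = "out"` restricts to outgoing edges.
#'
#' @param m an [AssociationMatrix-class].
#' @param mode `"total"` (in + out) or `"out"` for directed matrices;
#'   ignored for undirected ones.
#' @return Named numeric vector of strengths.
#' @export
setGeneric("strength", function(m, mode = "total") standardGeneric("strength"))

#' Weighted betweenness centrality
#'
#' Number of weighted shortest paths travelling through each individual,
#' with association weights converted to distances as 1/weight (stronger
#' ties are shorter), zero-weight dyads as non-edges, endpoints excluded,
#' fractional counting over tied shortest paths, and no normalization.
#' Unreachable pairs contribute nothing.
#'
#' @param m an [AssociationMatrix-class].
#' @return Named numeric vector of betweenness scores.
#' @export
setGeneric("betweenness", function(m) standardGeneric("betweenness"))
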