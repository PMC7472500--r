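#' Anatomical marker landmarks
#'
#' The landmark catalogue shared by the foot models: short code, anatomical
#' description, and the corresponding Rizzoli-style label used when renaming
#' mocap exports. `MC` and `IM` are computed midpoints (virtual markers),
#' never measured.
#'
#' @return A data.frame with columns `name`, `description`, `rizzoli_alias`,
#'   `virtual`.
#' @export
foot_landmarks <- function() {
  df <- data.frame(
    name = c("P1", "H1", "H2", "H5", "B1", "B2", "B5", "NV", "ST", "PT",
             "C1", "C2", "LM", "MM", "TT", "HF", "MC", "IM"),
    description = c(
      "Dorso-medial aspect of the first proximal phalanx head",
      "Dorso-medial aspect of the first metatarsal head",
      "Dorso-medial aspect of the second metatarsal head",
      "Dorso-lateral aspect of the fifth metatarsal head",
      "Dorso-medial aspect of the first metatarsal base",
      "Dorso-medial aspect of the second metatarsal base",
      "Dorso-lateral aspect of the fifth metatarsal base",
      "Most medial apex of the navicular bone",
      "Most medial apex of the sustentaculum tali",
      "Lateral apex of the peroneal tubercle",
      "Superior apex of calcaneus",
      "Apex of calcaneal tuberosity",
      "Distal apex of the lateral malleolus",
      "Distal apex of the medial malleolus",
      "Most anterior prominence of the tibial tuberosity",
      "Most proximal apex of the head of the fibula",
      "Midpoint between NV and B5",
      "Midpoint between MM and LM"),
    rizzoli_alias = c("PM", "FMH", "SMH", "VMH", "FMB", "SMB", "VMB", "TN",
                      "ST", "PT", "CA", "HL", "LM", "MM", "TT", "HF", "ID",
                      "IM"),
    virtual = c(rep(FALSE, 16), TRUE, TRUE),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(df$name))
  df
}

#' Rizzoli-style label aliases
#'
#' Named character vector mapping Rizzoli-style marker labels to the
#' canonical landmark codes, used to rename mocap exports automatically.
#'
#' @return Named character vector (alias -> canonical code).
#' @export
marker_aliases <- function() {
  lm <- foot_landmarks()
  stats::setNames(lm$name, lm$rizzoli_alias)
}

#' Define a segment reference frame
#'
#' A segment frame is built from a long-axis marker pair and a three-marker
#' plane. The long axis maps to the segment's anatomical primary axis
#' (anterior X for foot segments, superior Y for the shank); the plane's
#' unit normal supplies the second axis according to the plane label
#' (transverse -> superior Y, sagittal -> right-lateral Z, frontal ->
#' anterior X); the remaining axis completes a right-handed triad.
#'
#' `normal_sign` fixes the orientation of the ordered-triple cross product
#' `(m2 - m1) x (m3 - m1)` so it points along the required anatomical
#' direction. It is a constant of the definition (calibrated once from the
#' neutral anatomical position of a right foot) so that pose construction is
#' exactly equivariant under rigid motions. Left feet must be pre-mirrored
#' (negate lab Z) by the caller.
#'
#' @param name Segment name.
#' @param axis_from,axis_to Landmark codes of the long-axis pair (from -> to).
#' @param plane Character vector of the three plane landmarks, in order.
#' @param plane_label One of `"transverse"`, `"sagittal"`, `"frontal"`.
#' @param normal_sign `+1` or `-1`, see Details.
#' @param primary One of `"anterior"` (maps the long axis to X) or
#'   `"superior"` (maps it to Y).
#' @return An object of class `segment_definition`.
#' @export
segment_definition <- function(name, axis_from, axis_to, plane,
                               plane_label = c("transverse", "sagittal",
                                               "frontal"),
                               normal_sign = 1,
                               primary = c("anterior", "superior")) {
  plane_label <- match.arg(plane_label)
  primary <- match.arg(primary)
  stopifnot(is.character(name), length(name) == 1,
            is.character(plane), length(plane) == 3,
            normal_sign %in% c(-1, 1))
  structure(list(name = name, axis_from = axis_from, axis_to = axis_to,
                 plane = plane, plane_label = plane_label,
                 normal_sign = normal_sign, primary = primary),
            class = "segment_definition")
}

segment_markers <- function(segdef) {
  unique(c(segdef$axis_from, segdef$axis_to, segdef$plane))
}

new_model_segments <- function() {
  list(
    Hallux = segment_definition("Hallux", "H1", "P1",
                                c("H1", "P1", "H5"), "transverse", -1),
    Forefoot = segment_definition("Forefoot", "MC", "H2",
                                  c("MC", "H1", "H5"), "transverse", -1),
    Rearfoot = segment_definition("Rearfoot", "C1", "MC",
                                  c("C1", "NV", "B5"), "transverse", -1),
    Shank = segment_definition("Shank", "IM", "TT",
                               c("IM", "LM", "HF"), "frontal", -1,
                               primary = "superior")
  )
}

#' Foot model registry
#'
#' Returns the full declarative specification of one of the three built-in
#' multi-segment foot models:
#'
#' * `"new"` — three foot segments (hallux, forefoot, rearfoot) plus shank,
#'   with transverse-plane segment frames; rearfoot long axis `C1 -> MC`.
#' * `"new_2"` — identical to `"new"` except for the rearfoot, which is
#'   defined in the sagittal plane (`C2 -> MC`, plane `C2, MC, C1`); its
#'   joints are reported as `Cal_Met_2` / `Sha_Cal_2`.
#' * `"rizzoli"` — a Rizzoli-style reference model reconstructed from the
#'   landmark alias catalogue and the published segment descriptions
#'   (hallux, metatarsus, calcaneus, shank). The exact frame constructions
#'   of the original are not restated here; these are documented,
#'   reconstructed-from-citation definitions using the same primary-axis +
#'   plane machinery.
#'
#' Joints are distal-relative-to-proximal: `Met_Hal` (hallux relative to
#' forefoot), `Cal_Met` (forefoot relative to rearfoot), `Sha_Cal` (rearfoot
#' relative to shank), with `_2` variants against the sagittal rearfoot.
#'
#' @param model_id One of `"new"`, `"new_2"`, `"rizzoli"`.
#' @return An object of class `foot_model`: list with `model_id`,
#'   `landmarks`, `virtual` (virtual marker -> parent pair), `segments`
#'   (named list of [segment_definition()]s) and `joints` (data.frame
#'   `joint`, `child`, `parent`).
#' @examples
#' m <- register_model("new")
#' m$segments$Hallux
#' @export
register_model <- function(model_id) {
  if (!is.character(model_id) || length(model_id) != 1 ||
      !(model_id %in% c("new", "new_2", "rizzoli"))) {
    stop("unknown model id: ", paste(model_id, collapse = ", "),
         " (supported: new, new_2, rizzoli)")
  }
  virtual <- list(MC = c("NV", "B5"), IM = c("MM", "LM"))
  if (model_id == "new") {
    segments <- new_model_segments()
    joints <- data.frame(
      joint = c("Met_Hal", "Cal_Met", "Sha_Cal"),
      child = c("Hallux", "Forefoot", "Rearfoot"),
      parent = c("Forefoot", "Rearfoot", "Shank"),
      stringsAsFactors = FALSE)
  } else if (model_id == "new_2") {
    segments <- new_model_segments()
    segments$Rearfoot <- NULL
    segments <- append(segments, list(
      Rearfoot_2 = segment_definition("Rearfoot_2", "C2", "MC",
                                      c("C2", "MC", "C1"), "sagittal", 1)),
      after = 2)
    joints <- data.frame(
      joint = c("Met_Hal", "Cal_Met_2", "Sha_Cal_2"),
      child = c("Hallux", "Forefoot", "Rearfoot_2"),
      parent = c("Forefoot", "Rearfoot_2", "Shank"),
      stringsAsFactors = FALSE)
  } else {
    segments <- list(
      Hallux = segment_definition("Hallux", "H1", "P1",
                                  c("H1", "P1", "H5"), "transverse", -1),
      Metatarsus = segment_definition("Metatarsus", "B2", "H2",
                                      c("B2", "H1", "H5"), "transverse", -1),
      Calcaneus = segment_definition("Calcaneus", "C1", "MC",
                                     c("C1", "ST", "PT"), "transverse", -1),
      Shank = segment_definition("Shank", "IM", "TT",
                                 c("IM", "LM", "HF"), "frontal", -1,
                                 primary = "superior")
    )
    joints <- data.frame(
      joint = c("Met_Hal", "Cal_Met", "Sha_Cal"),
      child = c("Hallux", "Metatarsus", "Calcaneus"),
      parent = c("Metatarsus", "Calcaneus", "Shank"),
      stringsAsFactors = FALSE)
  }
  lm <- foot_landmarks()
  for (s in segments) {
    stopifnot(all(segment_markers(s) %in% lm$name))
  }
  stopifnot(all(joints$child %in% names(segments)),
            all(joints$parent %in% names(segments)))
  structure(list(model_id = model_id, landmarks = lm, virtual = virtual,
                 segments = segments, joints = joints),
            class = "foot_model")
}

#' @export
print.foot_model <- function(x, ...) {
  cat("<foot_model> ", x$model_id, "\n", sep = "")
  for (s in x$segments) {
    cat(sprintf("  %-11s %s -> %-3s plane (%s) %s\n", s$name, s$axis_from,
                s$axis_to, paste(s$plane, collapse = ", "), s$plane_label))
  }
  cat("  joints: ", paste(x$joints$joint, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
print.segment_definition <- function(x, ...) {
  cat(sprintf("<segment_definition> %s: %s -> %s, plane (%s, %s), primary %s\n",
              x$name, x$axis_from, x$axis_to,
              paste(x$plane, collapse = ", "), x$plane_label, x$primary))
  invisible(x)
}

#' Serialize a foot model to YAML
#'
#' Writes the declarative model specification (segments, joints, virtual
#' markers) so users can edit or define custom models without code changes.
#'
#' @param model A `foot_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [model_from_yaml()]
#' @export
model_to_yaml <- function(model, path) {
  stopifnot(inherits(model, "foot_model"))
  spec <- list(
    model_id = model$model_id,
    virtual = lapply(model$virtual, as.list),
    segments = lapply(unname(model$segments), function(s) {
      list(name = s$name, axis_from = s$axis_from, axis_to = s$axis_to,
           plane = as.list(s$plane), plane_label = s$plane_label,
           normal_sign = s$normal_sign, primary = s$primary)
    }),
    joints = lapply(seq_len(nrow(model$joints)), function(i) {
      as.list(model$joints[i, c("joint", "child", "parent")])
    })
  )
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' Read a foot model from YAML
#'
#' @param path YAML file produced by [model_to_yaml()] or hand-written in the
#'   same schema.
#' @return A `foot_model`.
#' @export
model_from_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  segments <- lapply(spec$segments, function(s) {
    segment_definition(s$name, s$axis_from, s$axis_to,
                       unlist(s$plane), s$plane_label,
                       normal_sign = s$normal_sign, primary = s$primary)
  })
  names(segments) <- vapply(segments, `[[`, character(1), "name")
  joints <- do.call(rbind, lapply(spec$joints, function(j) {
    data.frame(joint = j$joint, child = j$child, parent = j$parent,
               stringsAsFactors = FALSE)
  }))
  stopifnot(all(joints$child %in% names(segments)),
            all(joints$parent %in% names(segments)))
  structure(list(model_id = spec$model_id, landmarks = foot_landmarks(),
                 virtual = lapply(spec$virtual, unlist),
                 segments = segments, joints = joints),
            class = "foot_model")
}
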