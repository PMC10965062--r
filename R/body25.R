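#' BODY_25 keypoint names
#'
#' Keypoint labels of the 25-keypoint human body model, in the order the pose
#' estimator writes them (index 0 = nose ... index 24 = right heel).
#'
#' @format Character vector of length 25.
#' @export
body25_keypoints <- c(
  "nose", "neck",
  "r_shoulder", "r_elbow", "r_wrist",
  "l_shoulder", "l_elbow", "l_wrist",
  "mid_hip",
  "r_hip", "r_knee", "r_ankle",
  "l_hip", "l_knee", "l_ankle",
  "r_eye", "l_eye", "r_ear", "l_ear",
  "l_big_toe", "l_small_toe", "l_heel",
  "r_big_toe", "r_small_toe", "r_heel"
)

# left/right keypoint pairs, lower-limb pairs first (those drive gait and are
# the ones examined by the label-swap corrector)
body25_pairs <- function(lower_limb_only = FALSE) {
  lower <- list(
    c("l_hip", "r_hip"), c("l_knee", "r_knee"), c("l_ankle", "r_ankle"),
    c("l_heel", "r_heel"), c("l_big_toe", "r_big_toe"),
    c("l_small_toe", "r_small_toe")
  )
  if (lower_limb_only) return(lower)
  c(lower, list(
    c("l_shoulder", "r_shoulder"), c("l_elbow", "r_elbow"),
    c("l_wrist", "r_wrist"), c("l_eye", "r_eye"), c("l_ear", "r_ear")
  ))
}
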