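# Default configuration of the bccmap pipeline.
#
# inlier_accept_threshold       registration accepted only when RANSAC
#                               inliers are strictly above this count
# mosaic_max_frames             maximum frames stitched into one mosaic
# ransac_inlier_tol_px          inlier residual tolerance, reference px
# ransac_max_iters              RANSAC hypotheses per estimate
# tracking_confidence_threshold inter-frame inlier count gate (strict)
# tracking_max_coast            max consecutive dead-reckoned frames
# patch_size_px/patch_stride_px heatmap patch grid geometry
# patch_score_threshold         percent score below which patches are
#                               suppressed in the heatmap
# detector_*                    keypoint detector settings
# match_cross_check             optional symmetric match filter (off: plain
#                               one-way nearest-neighbor matching)
# heatmap_per_patch_color       diagnostic per-patch coloring (off: retained
#                               patches take the frame's global score color)
# calibrations                  physical FOV (mm) and pixel dimensions per
#                               imaging modality
inlier_accept_threshold: 6
mosaic_max_frames: 40
ransac_inlier_tol_px: 3.0
ransac_max_iters: 2000
tracking_confidence_threshold: 6
tracking_max_coast: 25
patch_size_px: 128
patch_stride_px: 64
patch_score_threshold: 50.0
detector_contrast: 0.03
detector_edge: 10.0
detector_sigma0: 1.6
detector_scales: 3
match_cross_check: no
heatmap_per_patch_color: no
calibrations:
  dermoscope:
    modality: dermoscope
    fov:
    - 13.3
    - 8.9
    image_shape:
    - 5536
    - 3692
    circular: no
  surface:
    modality: surface
    fov: 2.6
    image_shape:
    - 400
    - 400
    circular: yes
  lcoct_vertical:
    modality: lcoct_vertical
    fov:
    - 1.2
    - 0.4
    image_shape:
    - 2048
    - 680
    circular: no
  lcoct_horizontal:
    modality: lcoct_horizontal
    fov:
    - 1.2
    - 0.5
    image_shape:
    - 2048
    - 850
    circular: no
  lcoct_3d:
    modality: lcoct_3d
    fov:
    - 1.2
    - 0.5
    image_shape:
    - 1200
    - 500
    circular: no
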