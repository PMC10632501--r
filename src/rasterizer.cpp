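// Z-buffered triangle rasterizer producing the co-registered geometry
// buffers (depth, instance id, normals, albedo, world position) from which
// the image passes are assembled in R.
//
// Pixel convention: 0-based, origin top-left, centers at integer + 0.5.
// Depth is the camera-plane distance (camera-space z). Depth and
// vertex attributes are interpolated perspective-correctly (1/z linear in
// screen space).

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List rasterize_cpp(NumericMatrix verts_cam,   // n x 3 camera-space positions
                   NumericMatrix verts_world, // n x 3 world positions
                   IntegerMatrix tris,        // m x 3, 1-based
                   NumericMatrix albedo,      // n x 3 per-vertex color
                   NumericMatrix id_col,      // m x 3 per-triangle id color
                   NumericMatrix nrm_world,   // m x 3 per-triangle normal
                   NumericMatrix nrm_view,    // m x 3 per-triangle view normal
                   int W, int H,
                   double fx, double fy, double cx, double cy,
                   double znear) {
  const int npix = W * H;
  NumericVector depth(npix, R_PosInf);
  NumericVector idr(npix), idg(npix), idb(npix);
  NumericVector nwx(npix), nwy(npix), nwz(npix);
  NumericVector nvx(npix), nvy(npix), nvz(npix);
  NumericVector alr(npix), alg(npix), alb(npix);
  NumericVector wpx(npix), wpy(npix), wpz(npix);
  IntegerVector covered(npix, 0);

  const int m = tris.nrow();
  for (int t = 0; t < m; ++t) {
    int ia = tris(t, 0) - 1, ib = tris(t, 1) - 1, ic = tris(t, 2) - 1;
    double za = verts_cam(ia, 2), zb = verts_cam(ib, 2), zc = verts_cam(ic, 2);
    // no near-plane clipping: triangles crossing the near plane are skipped
    if (za < znear || zb < znear || zc < znear) continue;
    double ax = cx + fx * verts_cam(ia, 0) / za, ay = cy + fy * verts_cam(ia, 1) / za;
    double bx = cx + fx * verts_cam(ib, 0) / zb, by = cy + fy * verts_cam(ib, 1) / zb;
    double gx = cx + fx * verts_cam(ic, 0) / zc, gy = cy + fy * verts_cam(ic, 1) / zc;

    double area = (bx - ax) * (gy - ay) - (by - ay) * (gx - ax);
    if (area == 0.0) continue;

    int x0 = std::max(0, (int)std::floor(std::min(ax, std::min(bx, gx)) - 0.5));
    int x1 = std::min(W - 1, (int)std::ceil(std::max(ax, std::max(bx, gx)) - 0.5));
    int y0 = std::max(0, (int)std::floor(std::min(ay, std::min(by, gy)) - 0.5));
    int y1 = std::min(H - 1, (int)std::ceil(std::max(ay, std::max(by, gy)) - 0.5));
    if (x1 < x0 || y1 < y0) continue;

    double iza = 1.0 / za, izb = 1.0 / zb, izc = 1.0 / zc;
    for (int py = y0; py <= y1; ++py) {
      double sy = py + 0.5;
      for (int px = x0; px <= x1; ++px) {
        double sx = px + 0.5;
        double w0 = ((bx - ax) * (sy - ay) - (by - ay) * (sx - ax)) / area; // weight of c
        double w1 = ((gx - bx) * (sy - by) - (gy - by) * (sx - bx)) / area; // weight of a
        double w2 = 1.0 - w0 - w1;                                          // weight of b
        // w1 -> a, w2 -> b, w0 -> c
        if (w0 < 0 || w1 < 0 || w2 < 0) continue;
        double iz = w1 * iza + w2 * izb + w0 * izc;
        double z = 1.0 / iz;
        int idx = py * W + px;   // row-major rows = scanlines
        if (z >= depth[idx]) continue;
        depth[idx] = z;
        covered[idx] = 1;
        double wa = w1 * iza * z, wb = w2 * izb * z, wc = w0 * izc * z;
        alr[idx] = wa * albedo(ia, 0) + wb * albedo(ib, 0) + wc * albedo(ic, 0);
        alg[idx] = wa * albedo(ia, 1) + wb * albedo(ib, 1) + wc * albedo(ic, 1);
        alb[idx] = wa * albedo(ia, 2) + wb * albedo(ib, 2) + wc * albedo(ic, 2);
        wpx[idx] = wa * verts_world(ia, 0) + wb * verts_world(ib, 0) + wc * verts_world(ic, 0);
        wpy[idx] = wa * verts_world(ia, 1) + wb * verts_world(ib, 1) + wc * verts_world(ic, 1);
        wpz[idx] = wa * verts_world(ia, 2) + wb * verts_world(ib, 2) + wc * verts_world(ic, 2);
        idr[idx] = id_col(t, 0); idg[idx] = id_col(t, 1); idb[idx] = id_col(t, 2);
        nwx[idx] = nrm_world(t, 0); nwy[idx] = nrm_world(t, 1); nwz[idx] = nrm_world(t, 2);
        nvx[idx] = nrm_view(t, 0); nvy[idx] = nrm_view(t, 1); nvz[idx] = nrm_view(t, 2);
      }
    }
  }

  return List::create(
    _["depth"] = depth, _["covered"] = covered,
    _["id_r"] = idr, _["id_g"] = idg, _["id_b"] = idb,
    _["albedo_r"] = alr, _["albedo_g"] = alg, _["albedo_b"] = alb,
    _["nw_x"] = nwx, _["nw_y"] = nwy, _["nw_z"] = nwz,
    _["nv_x"] = nvx, _["nv_y"] = nvy, _["nv_z"] = nvz,
    _["wp_x"] = wpx, _["wp_y"] = wpy, _["wp_z"] = wpz);
}
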