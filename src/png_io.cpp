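// Minimal 8-bit PNG reader/writer backed by the system zlib.
// Supports non-interlaced images, bit depth 8, color types 0 (gray),
// 2 (RGB), 4 (gray+alpha), 6 (RGBA). Color is collapsed to luminance on
// read. Sufficient for grayscale OCTA images and binary masks; anything
// fancier (palettes, 16-bit, interlacing) is rejected with an error.
#include <Rcpp.h>
#include <zlib.h>
#include <cstdio>
#include <cstring>
#include <vector>
#include <string>

using namespace Rcpp;

namespace {

void put_u32(std::vector<unsigned char>& v, uint32_t x) {
  v.push_back((x >> 24) & 0xff);
  v.push_back((x >> 16) & 0xff);
  v.push_back((x >> 8) & 0xff);
  v.push_back(x & 0xff);
}

uint32_t get_u32(const unsigned char* p) {
  return (uint32_t(p[0]) << 24) | (uint32_t(p[1]) << 16) |
         (uint32_t(p[2]) << 8) | uint32_t(p[3]);
}

void write_chunk(std::vector<unsigned char>& out, const char* type,
                 const unsigned char* data, size_t n) {
  put_u32(out, (uint32_t)n);
  size_t start = out.size();
  out.insert(out.end(), type, type + 4);
  if (n) out.insert(out.end(), data, data + n);
  uLong crc = crc32(0L, Z_NULL, 0);
  crc = crc32(crc, out.data() + start, (uInt)(n + 4));
  put_u32(out, (uint32_t)crc);
}

} // namespace

// [[Rcpp::export(name = ".png_write_gray")]]
void png_write_gray_cpp(std::string path, IntegerMatrix img) {
  int H = img.nrow(), W = img.ncol();
  if (H < 1 || W < 1) stop("empty image");
  // raw scanlines: filter byte 0 + W gray bytes per row
  std::vector<unsigned char> raw((size_t)H * (W + 1));
  for (int r = 0; r < H; ++r) {
    unsigned char* row = raw.data() + (size_t)r * (W + 1);
    row[0] = 0;
    for (int c = 0; c < W; ++c) {
      int v = img(r, c);
      if (v < 0) v = 0;
      if (v > 255) v = 255;
      row[1 + c] = (unsigned char)v;
    }
  }
  uLongf comp_len = compressBound((uLong)raw.size());
  std::vector<unsigned char> comp(comp_len);
  if (compress2(comp.data(), &comp_len, raw.data(), (uLong)raw.size(), 6) != Z_OK)
    stop("zlib compression failed");
  comp.resize(comp_len);

  std::vector<unsigned char> out;
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  out.insert(out.end(), sig, sig + 8);
  unsigned char ihdr[13];
  ihdr[0] = (W >> 24) & 0xff; ihdr[1] = (W >> 16) & 0xff;
  ihdr[2] = (W >> 8) & 0xff;  ihdr[3] = W & 0xff;
  ihdr[4] = (H >> 24) & 0xff; ihdr[5] = (H >> 16) & 0xff;
  ihdr[6] = (H >> 8) & 0xff;  ihdr[7] = H & 0xff;
  ihdr[8] = 8;   // bit depth
  ihdr[9] = 0;   // color type: grayscale
  ihdr[10] = 0; ihdr[11] = 0; ihdr[12] = 0;
  write_chunk(out, "IHDR", ihdr, 13);
  write_chunk(out, "IDAT", comp.data(), comp.size());
  write_chunk(out, "IEND", nullptr, 0);

  FILE* f = std::fopen(path.c_str(), "wb");
  if (!f) stop("cannot open '%s' for writing", path.c_str());
  size_t written = std::fwrite(out.data(), 1, out.size(), f);
  std::fclose(f);
  if (written != out.size()) stop("short write to '%s'", path.c_str());
}

// [[Rcpp::export(name = ".png_read_gray")]]
IntegerMatrix png_read_gray_cpp(std::string path) {
  FILE* f = std::fopen(path.c_str(), "rb");
  if (!f) stop("cannot open '%s'", path.c_str());
  std::fseek(f, 0, SEEK_END);
  long sz = std::ftell(f);
  std::fseek(f, 0, SEEK_SET);
  std::vector<unsigned char> buf((size_t)sz);
  size_t got = std::fread(buf.data(), 1, (size_t)sz, f);
  std::fclose(f);
  if ((long)got != sz || sz < 8) stop("cannot read '%s'", path.c_str());
  const unsigned char sig[8] = {137, 80, 78, 71, 13, 10, 26, 10};
  if (std::memcmp(buf.data(), sig, 8) != 0)
    stop("'%s' is not a PNG file", path.c_str());

  size_t pos = 8;
  int W = 0, H = 0, bit_depth = 0, color_type = 0, interlace = 0;
  std::vector<unsigned char> idat;
  bool seen_ihdr = false;
  while (pos + 8 <= buf.size()) {
    uint32_t len = get_u32(buf.data() + pos);
    const char* type = (const char*)buf.data() + pos + 4;
    if (pos + 12 + len > buf.size()) stop("truncated PNG chunk in '%s'", path.c_str());
    const unsigned char* data = buf.data() + pos + 8;
    if (std::memcmp(type, "IHDR", 4) == 0) {
      if (len != 13) stop("bad IHDR");
      W = (int)get_u32(data);
      H = (int)get_u32(data + 4);
      bit_depth = data[8];
      color_type = data[9];
      interlace = data[12];
      seen_ihdr = true;
    } else if (std::memcmp(type, "IDAT", 4) == 0) {
      idat.insert(idat.end(), data, data + len);
    } else if (std::memcmp(type, "IEND", 4) == 0) {
      break;
    }
    pos += 12 + len;
  }
  if (!seen_ihdr || idat.empty()) stop("malformed PNG '%s'", path.c_str());
  if (bit_depth != 8) stop("unsupported PNG bit depth %d (only 8)", bit_depth);
  if (interlace != 0) stop("interlaced PNG not supported");
  int nch;
  switch (color_type) {
    case 0: nch = 1; break;
    case 2: nch = 3; break;
    case 4: nch = 2; break;
    case 6: nch = 4; break;
    default: stop("unsupported PNG color type %d", color_type);
  }

  size_t stride = (size_t)W * nch;
  std::vector<unsigned char> raw(H * (stride + 1));
  uLongf raw_len = (uLongf)raw.size();
  int zrc = uncompress(raw.data(), &raw_len, idat.data(), (uLong)idat.size());
  if (zrc != Z_OK || raw_len != raw.size()) stop("PNG inflate failed for '%s'", path.c_str());

  // undo scanline filters in place
  std::vector<unsigned char> prev(stride, 0);
  IntegerMatrix img(H, W);
  int bpp = nch;
  for (int r = 0; r < H; ++r) {
    unsigned char* row = raw.data() + (size_t)r * (stride + 1);
    int filt = row[0];
    unsigned char* cur = row + 1;
    for (size_t i = 0; i < stride; ++i) {
      int a = (i >= (size_t)bpp) ? cur[i - bpp] : 0;
      int b = prev[i];
      int c = (i >= (size_t)bpp) ? prev[i - bpp] : 0;
      int x = cur[i];
      switch (filt) {
        case 0: break;
        case 1: x += a; break;
        case 2: x += b; break;
        case 3: x += (a + b) / 2; break;
        case 4: {
          int p = a + b - c;
          int pa = std::abs(p - a), pb = std::abs(p - b), pc = std::abs(p - c);
          x += (pa <= pb && pa <= pc) ? a : (pb <= pc ? b : c);
          break;
        }
        default: stop("unsupported PNG filter %d", filt);
      }
      cur[i] = (unsigned char)(x & 0xff);
    }
    std::memcpy(prev.data(), cur, stride);
    for (int cidx = 0; cidx < W; ++cidx) {
      const unsigned char* px = cur + (size_t)cidx * nch;
      int g;
      if (nch == 1 || nch == 2) {
        g = px[0];
      } else {
        // ITU-R BT.601 luminance, rounded
        g = (int)(0.299 * px[0] + 0.587 * px[1] + 0.114 * px[2] + 0.5);
      }
      img(r, cidx) = g;
    }
  }
  return img;
}

// [[Rcpp::export(name = ".crc32_bytes")]]
double crc32_bytes_cpp(RawVector bytes) {
  uLong crc = crc32(0L, Z_NULL, 0);
  if (bytes.size() > 0)
    crc = crc32(crc, (const Bytef*)RAW(bytes), (uInt)bytes.size());
  return (double)crc;
}
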